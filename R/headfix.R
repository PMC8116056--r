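# Head-fixation training: headport-entry luring, fixation-duration ramp,
# adaptive self-release thresholds, release-type resolution from the
# load-sensing platform, and body-weight estimation.

#' Head-fixation training state
#'
#' @param fixation_duration Initial scheduled fixation duration (seconds).
#' @param release_thresholds Numeric `c(lower, upper)` in grams; a load
#'   reading outside the open interval releases the clamps.
#' @return An object of class `headfix_state`.
#' @export
headfix_state <- function(fixation_duration = 3,
                          release_thresholds = c(lower = -1, upper = 30)) {
  structure(list(subprotocol = "headport_entry",
                 lickport_distance = 0,          # mm from home-cage position
                 rewarded_licks_since_retraction = 0L,
                 switch_trigger_count = 0L,
                 rewarded_spout = "left",
                 rewards_on_current_spout = 0L,
                 fixation_duration = fixation_duration,
                 timeup_count_since_increment = 0L,
                 clamp_mode = "soft",
                 clamp_pressure = 1.78,          # bar (2.78 after 2 s in hard)
                 release_thresholds = c(lower = release_thresholds[[1]],
                                        upper = release_thresholds[[2]]),
                 recent_releases = character(0), # ring of last 20 types
                 phase = "training"),            # "training" or "extension"
            class = "headfix_state")
}

HEADPORT_RETRACT_STEP <- 3     # mm per 20 rewarded licks
HEADPORT_MAX_DISTANCE <- 14    # mm; lickport only reachable from the headport
HEADPORT_SWITCH_GOAL <- 30L    # switch triggers to advance
FIXATION_INCREMENT <- 2        # seconds added per 20 time-up releases
FIXATION_BATCH <- 20L
HARD_CLAMP_AT <- 10            # seconds
TRAINING_CAP <- 30             # seconds; completes the subprotocol
EXTENSION_CAP <- 60            # seconds; post-task extension
THRESHOLD_STEP <- 2            # grams
MIN_THRESHOLD_WIDTH <- 10      # grams; narrowing floor

#' Step the headport-entry subprotocol
#'
#' Mice are lured into the headport by a lickport that retracts one 3 mm
#' step after every 20 rewarded licks until it sits ~14 mm from the headport,
#' where licking requires triggering the mechanical switches at the end of
#' the guide tracks.  The rewarded spout alternates after three rewards per
#' side.  Twelve hours without licks re-extends the lickport; thirty switch
#' triggers advance to the head-fixation subprotocol.
#'
#' @param state A `headfix_state` with `subprotocol == "headport_entry"`.
#' @param event One of `"rewarded_lick"`, `"switch_trigger"`,
#'   `"no_licks_12h"`.
#' @return The updated state.
#' @export
step_headport_entry <- function(state, event) {
  stopifnot(inherits(state, "headfix_state"))
  if (state$subprotocol != "headport_entry")
    stop("headport-entry events after the subprotocol completed")
  event <- match.arg(event, c("rewarded_lick", "switch_trigger",
                              "no_licks_12h"))
  if (event == "rewarded_lick") {
    state$rewarded_licks_since_retraction <-
      state$rewarded_licks_since_retraction + 1L
    state$rewards_on_current_spout <- state$rewards_on_current_spout + 1L
    if (state$rewards_on_current_spout >= 3L) {
      state$rewarded_spout <- if (state$rewarded_spout == "left") "right"
      else "left"
      state$rewards_on_current_spout <- 0L
    }
    if (state$rewarded_licks_since_retraction >= 20L) {
      state$lickport_distance <- min(state$lickport_distance +
                                       HEADPORT_RETRACT_STEP,
                                     HEADPORT_MAX_DISTANCE)
      state$rewarded_licks_since_retraction <- 0L
    }
  } else if (event == "switch_trigger") {
    state$switch_trigger_count <- state$switch_trigger_count + 1L
    if (state$switch_trigger_count >= HEADPORT_SWITCH_GOAL)
      state$subprotocol <- "head_fixation"
  } else {
    state$lickport_distance <- 0
    state$rewarded_licks_since_retraction <- 0L
  }
  state
}

#' Step the fixation-duration schedule
#'
#' The scheduled duration starts at 3 s and increases by 2 s after every 20
#' time-up releases (escapes and self-releases do not count).  Fixation
#' switches from soft to hard clamp once the duration reaches 10 s.  The
#' training subprotocol completes when the duration reaches 30 s; the
#' post-task extension continues the same schedule from 30 to 60 s.
#'
#' @param state A `headfix_state`.
#' @param release_type `"time_up"`, `"escape"`, or `"self_release"`.
#' @return The updated state; `state$subprotocol` becomes `"complete"` when
#'   the training cap is reached.
#' @export
step_fixation_training <- function(state, release_type) {
  stopifnot(inherits(state, "headfix_state"))
  release_type <- match.arg(release_type,
                            c("time_up", "escape", "self_release"))
  state$recent_releases <- utils::tail(c(state$recent_releases, release_type),
                                       20L)
  if (length(state$recent_releases) == 20L)
    state$release_thresholds <-
      update_release_thresholds(state$recent_releases,
                                state$release_thresholds)
  cap <- if (state$phase == "training") TRAINING_CAP else EXTENSION_CAP
  if (release_type == "time_up" && state$fixation_duration < cap) {
    state$timeup_count_since_increment <-
      state$timeup_count_since_increment + 1L
    if (state$timeup_count_since_increment >= FIXATION_BATCH) {
      state$fixation_duration <- state$fixation_duration + FIXATION_INCREMENT
      state$timeup_count_since_increment <- 0L
      if (state$fixation_duration >= cap) {
        state$fixation_duration <- cap
        if (state$phase == "training") state$subprotocol <- "complete"
      }
    }
  }
  state$clamp_mode <- if (state$fixation_duration >= HARD_CLAMP_AT) "hard"
  else "soft"
  state
}

#' Adapt the self-release thresholds
#'
#' The platform releases the clamps whenever the load reading leaves the
#' open interval `(lower, upper)` (initially (-1, 30) g).  Based on the last
#' 20 head-fixations: if more than 90% ended in self-release the band widens
#' by 2 g on each side; if fewer than 5% did, it narrows by 2 g on each side,
#' down to a minimum width of 10 g.
#'
#' @param recent Character vector of exactly 20 release types.
#' @param thresholds Numeric `c(lower, upper)` grams.
#' @return The updated `c(lower, upper)`.
#' @export
update_release_thresholds <- function(recent, thresholds) {
  if (length(recent) != 20L)
    stop("threshold adaptation uses exactly the last 20 head-fixations")
  frac <- mean(recent == "self_release")
  lower <- thresholds[[1]]; upper <- thresholds[[2]]
  if (frac > 0.9) {
    lower <- lower - THRESHOLD_STEP
    upper <- upper + THRESHOLD_STEP
  } else if (frac < 0.05) {
    if ((upper - THRESHOLD_STEP) - (lower + THRESHOLD_STEP) >=
        MIN_THRESHOLD_WIDTH) {
      lower <- lower + THRESHOLD_STEP
      upper <- upper - THRESHOLD_STEP
    }
  }
  c(lower = lower, upper = upper)
}

#' Resolve how a head-fixation ends
#'
#' Three release scenarios compete in time order: an `escape` when the
#' switches disengage within the first 0.2 s (before the pistons clamp), a
#' `self_release` at the first load sample outside the threshold band, and a
#' `time_up` release when the scheduled duration elapses.
#'
#' @param load Data frame with columns `time` (seconds from clamp onset) and
#'   `weight` (grams, signed), nominally 20 samples/s.
#' @param switch_disengage_time Time the switches stopped being triggered,
#'   or `Inf` if they stayed engaged.
#' @param scheduled Scheduled fixation duration (seconds).
#' @param thresholds Numeric `c(lower, upper)` grams.
#' @param clamp_delay Seconds before the pistons hold (escape window).
#' @return A list with `type` (`"time_up"`, `"escape"`, `"self_release"`)
#'   and `time` (seconds from clamp onset).
#' @export
resolve_release <- function(load, switch_disengage_time = Inf,
                            scheduled = 30,
                            thresholds = c(lower = -1, upper = 30),
                            clamp_delay = 0.2) {
  if (is.finite(switch_disengage_time) &&
      switch_disengage_time < clamp_delay)
    return(list(type = "escape", time = switch_disengage_time))
  if (!is.null(load) && nrow(load) > 0L) {
    out <- load$time < scheduled &
      (load$weight <= thresholds[[1]] | load$weight >= thresholds[[2]])
    if (any(out)) {
      i <- which(out)[1L]
      return(list(type = "self_release", time = load$time[i]))
    }
  }
  list(type = "time_up", time = scheduled)
}

#' Estimate body weight from the load-sensing platform
#'
#' A day of 20 Hz load readings is dominated by the mouse resting on the
#' platform; the mode of the histogram of on-platform readings estimates the
#' body weight.  Readings at or below a small positive floor (platform
#' unoccupied or partial steps) are excluded.
#'
#' @param samples Data frame with columns `time` and `weight` (grams), or a
#'   numeric vector of weights.
#' @param bin_width Histogram bin width in grams.
#' @param floor_g On-platform floor in grams.
#' @param min_samples Minimum number of on-platform samples required.
#' @return Estimated body weight in grams (center of the modal bin).
#' @export
estimate_body_weight <- function(samples, bin_width = 0.1, floor_g = 5,
                                 min_samples = 100L) {
  w <- if (is.data.frame(samples)) samples$weight else as.numeric(samples)
  w <- w[is.finite(w) & w > floor_g]
  if (length(w) < min_samples)
    stop("insufficient on-platform load samples for weight estimation")
  breaks <- seq(floor(min(w) / bin_width) * bin_width,
                ceiling(max(w) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- hist(w, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Simulate a load-cell trace during one head-fixation
#'
#' Generates a 20 Hz load trace: a small resting load (the head-fixed mouse
#' rests partially on the platform) plus struggle excursions arriving as a
#' Poisson process, each a one-sample signed deflection with exponentially
#' distributed amplitude.  Used to exercise [resolve_release()] and as the
#' literal counterpart of the analytic release sampling in the closed-loop
#' simulator.
#'
#' @param duration Seconds of trace to generate.
#' @param resting_load Mean resting load (grams).
#' @param struggle_rate Struggle events per second.
#' @param amp_mean Mean excursion amplitude (grams).
#' @param noise_sd Gaussian sensor noise (grams).
#' @param rate_hz Sampling rate (samples/s).
#' @return Data frame with columns `time`, `weight`.
#' @export
simulate_load_trace <- function(duration, resting_load = 5,
                                struggle_rate = 0.1, amp_mean = 15,
                                noise_sd = 0.2, rate_hz = 20) {
  n <- max(1L, floor(duration * rate_hz))
  time <- seq_len(n) / rate_hz
  weight <- resting_load + stats::rnorm(n, 0, noise_sd)
  k <- stats::rpois(1, struggle_rate * duration)
  if (k > 0) {
    at <- sample.int(n, min(k, n))
    amp <- stats::rexp(length(at), 1 / amp_mean) *
      sample(c(-1, 1), length(at), replace = TRUE)
    weight[at] <- weight[at] + amp
  }
  data.frame(time = time, weight = weight)
}
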