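# Single-trial finite-state machine for the delayed-response tactile task.
#
# A trial is sample (1.3 s: 0.2 s pole travel + 1.0 s presentation + 0.1 s
# into retraction) -> delay -> auditory go cue (0.1 s) -> response window
# (1.5 s) -> inter-trial interval (2.5 s), with an error timeout appended
# between response end and the ITI.  Time is event-driven and expressed in
# seconds from sample onset; timestamps are rounded to 0.1 ms, the task
# controller's resolution.

TIME_RES <- 1e-4

round_t <- function(x) round(x / TIME_RES) * TIME_RES

#' Trial configuration
#'
#' Durations of the task epochs and trial-outcome parameters.  Defaults are
#' the values used in the trained (full-delay) stage of the task.
#'
#' @param sample_duration Sample epoch duration in seconds (pole travel,
#'   presentation, and 0.1 s into retraction).
#' @param delay_duration Delay epoch duration in seconds; the training
#'   schedule uses 0.2 s (unenforced) through 1.3 s.
#' @param go_cue_duration Duration of the auditory go cue in seconds.
#' @param response_window Seconds after the go cue in which the first lick
#'   is registered as the choice.
#' @param inter_trial_interval Seconds between trials.
#' @param error_timeout Timeout in seconds appended after an error (2 s in
#'   the directional stage, 4 s afterwards).
#' @param early_lick_pause Pause in seconds inserted before an epoch restart
#'   when a premature lick occurs in a delay-enforcing stage.
#' @param enforce_delay Logical; whether pre-go licks restart the epoch in
#'   which they occur.
#' @param reward_volume Water reward in microliters.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(sample_duration = 1.3,
                         delay_duration = 1.3,
                         go_cue_duration = 0.1,
                         response_window = 1.5,
                         inter_trial_interval = 2.5,
                         error_timeout = 4,
                         early_lick_pause = 0.1,
                         enforce_delay = TRUE,
                         reward_volume = 2.5) {
  durs <- c(sample_duration = sample_duration, delay_duration = delay_duration,
            go_cue_duration = go_cue_duration, response_window = response_window,
            inter_trial_interval = inter_trial_interval,
            error_timeout = error_timeout, early_lick_pause = early_lick_pause)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all trial durations must be positive and finite")
  if (delay_duration < 0.2 || delay_duration > 1.3)
    stop("delay_duration must lie in [0.2, 1.3] seconds")
  structure(list(sample_duration = sample_duration,
                 delay_duration = delay_duration,
                 go_cue_duration = go_cue_duration,
                 response_window = response_window,
                 inter_trial_interval = inter_trial_interval,
                 error_timeout = error_timeout,
                 early_lick_pause = early_lick_pause,
                 enforce_delay = isTRUE(enforce_delay),
                 reward_volume = reward_volume),
            class = "trial_config")
}

#' Photostimulation assignment
#'
#' Tags a trial with a photostimulus: a 40 Hz sinusoid lasting 1.3 s with a
#' 100 ms linear offset ramp, starting at the beginning of the sample, delay,
#' or response epoch.
#'
#' @param epoch One of `"sample"`, `"delay"`, `"response"`.
#' @param intensity Light intensity in mW/mm^2 (the behavioral experiments
#'   span 0.3--3.5 mW/mm^2).
#' @return An object of class `photostim_assignment`.
#' @export
photostim_assignment <- function(epoch, intensity = 1.5) {
  epoch <- match.arg(epoch, c("sample", "delay", "response"))
  structure(list(epoch = epoch, intensity = intensity,
                 waveform = "40Hz_sinusoid", duration = 1.3,
                 offset_ramp = 0.1),
            class = "photostim_assignment")
}

#' Build the epoch timeline of a trial
#'
#' Lays out epoch boundaries in seconds from sample onset.  The go cue marks
#' the start of the response epoch (0.1 s after the pole retraction onset of
#' the last sample second has already elapsed inside the 1.3 s sample).  A
#' masking flash (10 Hz) covers sample start through response end on every
#' trial; the photostimulation window, when assigned, spans exactly 1.3 s
#' from the start of its epoch, with the last 100 ms flagged as the linear
#' offset ramp, even when that overruns a shorter delay.
#'
#' @param config A [trial_config()].
#' @param stim Optional [photostim_assignment()].
#' @return An object of class `epoch_timeline`: a list with
#'   `sample_start`, `sample_end`, `delay_end`, `go_time`, `response_end`,
#'   `trial_end`, `masking_flash`, and optionally `photostim_window`.
#' @export
build_timeline <- function(config, stim = NULL) {
  stopifnot(inherits(config, "trial_config"))
  sample_start <- 0
  sample_end <- round_t(config$sample_duration)
  delay_end <- round_t(sample_end + config$delay_duration)
  go_time <- delay_end             # go cue starts the response epoch
  response_end <- round_t(go_time + config$go_cue_duration +
                            config$response_window)
  trial_end <- round_t(response_end + config$inter_trial_interval)
  tl <- list(sample_start = sample_start, sample_end = sample_end,
             delay_end = delay_end, go_time = go_time,
             response_end = response_end, trial_end = trial_end,
             response_window = config$response_window,
             masking_flash = c(start = sample_start, end = response_end,
                               rate_hz = 10))
  if (!is.null(stim)) {
    if (!inherits(stim, "photostim_assignment"))
      stop("stim must be a photostim_assignment")
    start <- switch(stim$epoch,
                    sample = sample_start,
                    delay = sample_end,
                    response = go_time)
    tl$photostim_window <- c(start = start,
                             end = round_t(start + stim$duration),
                             ramp_start = round_t(start + stim$duration -
                                                    stim$offset_ramp))
  }
  structure(tl, class = "epoch_timeline")
}

#' Register the choice from a lick stream
#'
#' The choice is the spout of the first lick strictly after the go cue and
#' within the response window; a lick exactly at the go time is pre-go.  If
#' no lick falls in `(go_time, go_time + response_window]` the trial is an
#' ignore.
#'
#' @param licks A data frame with columns `time` (seconds, sorted
#'   increasing) and `spout` (`"left"`/`"right"`), or NULL/empty.
#' @param timeline An [build_timeline()] result.
#' @return `"left"`, `"right"`, or `"ignore"`.
#' @export
register_choice <- function(licks, timeline) {
  stopifnot(inherits(timeline, "epoch_timeline"))
  if (is.null(licks) || nrow(licks) == 0L) return("ignore")
  if (is.unsorted(licks$time)) stop("lick times must be sorted")
  win <- licks$time > timeline$go_time &
    licks$time <= timeline$go_time + timeline$response_window
  if (!any(win)) return("ignore")
  as.character(licks$spout[which(win)[1L]])
}

#' Apply the early-lick policy
#'
#' In delay-enforcing stages a lick before the go cue triggers a brief pause
#' (default 0.1 s) after which the trial resumes from the beginning of the
#' epoch (sample or delay) in which the lick occurred.  In earlier stages
#' mice are free to lick at any time and the timeline is unchanged.
#'
#' @param timeline Current `epoch_timeline`.
#' @param lick_time Time of the premature lick (seconds, `< go_time`).
#' @param config The trial's [trial_config()].
#' @param stage Training stage; only `"delay"` and later stages enforce.
#' @return The (possibly shifted) timeline, with attribute `"restarted"`
#'   set to the restarted epoch name or `NA`.
#' @export
apply_early_lick_policy <- function(timeline, lick_time, config,
                                    stage = "delay") {
  stopifnot(inherits(timeline, "epoch_timeline"))
  if (lick_time >= timeline$go_time)
    stop("early-lick policy applies only before the go cue")
  enforcing <- config$enforce_delay && stage %in% c("delay", "complete")
  if (!enforcing) {
    attr(timeline, "restarted") <- NA_character_
    return(timeline)
  }
  pause <- config$early_lick_pause
  if (lick_time < timeline$sample_end) {
    # restart the full sample epoch, then the delay follows as scheduled
    epoch <- "sample"
    timeline$sample_end <- round_t(lick_time + pause + config$sample_duration)
    timeline$delay_end <- round_t(timeline$sample_end + config$delay_duration)
  } else {
    epoch <- "delay"
    timeline$delay_end <- round_t(lick_time + pause + config$delay_duration)
  }
  timeline$go_time <- timeline$delay_end
  timeline$response_end <- round_t(timeline$go_time + config$go_cue_duration +
                                     config$response_window)
  timeline$trial_end <- round_t(timeline$response_end +
                                  config$inter_trial_interval)
  timeline$masking_flash["end"] <- timeline$response_end
  attr(timeline, "restarted") <- epoch
  timeline
}

#' Run one trial to completion
#'
#' Composes the timeline, early-lick policy, choice registration and outcome
#' assignment into a complete trial record.  `behavior` scripts the animal:
#' early licks are given as offsets into the epoch in which they are
#' emitted (each processed against the current, possibly restarted,
#' timeline), and the response is a latency from the go cue.
#'
#' @param config A [trial_config()].
#' @param behavior A list with elements `early` (data frame with columns
#'   `epoch` in `"sample"`/`"delay"`, `offset` seconds into that epoch, and
#'   `spout`; may be NULL) and `response` (list with `latency` seconds after
#'   the go cue and `spout`, or NULL for no response lick).
#' @param trial_type `"lick_left"` or `"lick_right"` (the rewarded
#'   direction for this trial).
#' @param stage Training stage (`"directional"`, `"discrimination"`,
#'   `"delay"`, `"complete"`).
#' @param contingency `"standard"` (anterior pole instructs lick left) or
#'   `"reversed"`.
#' @param stim Optional [photostim_assignment()].
#' @param trial_index Ordinal trial number.
#' @return An object of class `trial_record`; see Details.
#' @details The record carries `trial_type`, the pole position implied by
#'   the contingency, wall-clock `lick_events`, the registered `choice`,
#'   `outcome` (`correct`/`error`/`ignore`), `early_lick_count`,
#'   `reward` (logical), the realised `timeline`, and the total trial
#'   duration including any error timeout before the ITI.
#' @export
run_trial <- function(config, behavior, trial_type,
                      stage = "delay", contingency = "standard",
                      stim = NULL, trial_index = 1L) {
  trial_type <- match.arg(trial_type, c("lick_left", "lick_right"))
  contingency <- match.arg(contingency, c("standard", "reversed"))
  timeline <- build_timeline(config, stim)
  enforcing <- config$enforce_delay && stage %in% c("delay", "complete")
  licks <- list()
  early_n <- 0L

  early <- behavior$early
  if (!is.null(early) && nrow(early) > 0L) {
    for (i in seq_len(nrow(early))) {
      ep <- early$epoch[i]
      # offset into the current (possibly already-restarted) epoch
      t_lick <- if (ep == "sample") {
        round_t(timeline$sample_end - config$sample_duration +
                  min(early$offset[i], config$sample_duration - TIME_RES))
      } else {
        round_t(timeline$delay_end - config$delay_duration +
                  min(early$offset[i], config$delay_duration - TIME_RES))
      }
      if (t_lick >= timeline$go_time) next
      licks[[length(licks) + 1L]] <- data.frame(time = t_lick,
                                                spout = early$spout[i])
      if (enforcing) {
        timeline <- apply_early_lick_policy(timeline, t_lick, config, stage)
        early_n <- early_n + 1L
      }
    }
  }

  if (!is.null(behavior$response)) {
    t_resp <- round_t(timeline$go_time + behavior$response$latency)
    licks[[length(licks) + 1L]] <- data.frame(time = t_resp,
                                              spout = behavior$response$spout)
  }
  lick_events <- if (length(licks)) do.call(rbind, licks)
  else data.frame(time = numeric(0), spout = character(0))
  lick_events <- lick_events[order(lick_events$time), , drop = FALSE]
  rownames(lick_events) <- NULL

  choice <- register_choice(lick_events, timeline)
  outcome <- if (choice == "ignore") "ignore"
  else if ((choice == "left") == (trial_type == "lick_left")) "correct"
  else "error"
  reward <- outcome == "correct"
  timeout <- if (outcome == "error") config$error_timeout else 0
  trial_dur <- round_t(timeline$response_end + timeout +
                         config$inter_trial_interval)

  pole <- pole_position(trial_type, contingency)
  structure(list(trial_index = as.integer(trial_index),
                 trial_type = trial_type,
                 pole_position = pole,
                 contingency = contingency,
                 stage = stage,
                 delay_duration = config$delay_duration,
                 lick_events = lick_events,
                 choice = choice,
                 outcome = outcome,
                 reward = reward,
                 early_lick_count = early_n,
                 photostim = stim,
                 timeline = timeline,
                 trial_duration = trial_dur,
                 autoassist_flags = character(0)),
            class = "trial_record")
}

#' Pole position implied by trial type and contingency
#'
#' Under the standard sensorimotor contingency the anterior pole position
#' instructs lick left and the posterior position lick right; a contingency
#' reversal swaps the mapping.
#'
#' @param trial_type `"lick_left"` or `"lick_right"`.
#' @param contingency `"standard"` or `"reversed"`.
#' @return `"anterior"` or `"posterior"`.
#' @export
pole_position <- function(trial_type, contingency = "standard") {
  left <- trial_type == "lick_left"
  std <- contingency == "standard"
  ifelse(left == std, "anterior", "posterior")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial %d [%s, %s]: choice=%s outcome=%s early=%d%s\n",
              x$trial_index, x$trial_type, x$stage, x$choice, x$outcome,
              x$early_lick_count,
              if (!is.null(x$photostim))
                sprintf(" stim=%s", x$photostim$epoch) else ""))
  invisible(x)
}
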