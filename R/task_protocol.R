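# Task-training protocol: stage progression (directional licking ->
# discrimination -> delay), trial-type scheduling, the four auto-assist
# programs, contingency reversal, and the optogenetic trial scheduler.
#
# Histories are passed as data frames with (at least) columns `trial_type`
# ("lick_left"/"lick_right") and `outcome` ("correct"/"error"/"ignore").
# Performance criteria use scored (non-ignore) trials only, and criterion
# windows must be full before they are evaluated.

#' Task-protocol state
#'
#' @param stage Starting stage.
#' @param reversal_mode Logical; contingency-reversal training (no delay
#'   stage; the protocol stays in discrimination and flips the contingency
#'   on criterion).
#' @return An object of class `task_state`.
#' @export
task_state <- function(stage = "directional", reversal_mode = FALSE) {
  structure(list(stage = stage,
                 contingency = "standard",
                 reversal_mode = isTRUE(reversal_mode),
                 n_reversals = 0L,
                 delay_duration = 0.2,    # nominal, unenforced before delay stage
                 scored_since_change = 0L, # scored trials since stage/delay/flip change
                 block_type = "lick_left",
                 block_correct = 0L,
                 forced_repeat_type = NA_character_,
                 forced_repeat_correct = 0L,
                 trial_type_probabilities = c(lick_left = 0.5,
                                              lick_right = 0.5),
                 lickport_offset = 0),    # mm; + moves right spout closer
            class = "task_state")
}

scored <- function(history) history[history$outcome != "ignore", , drop = FALSE]

perf_last <- function(history, n) {
  s <- scored(history)
  if (nrow(s) < n) return(NA_real_)
  mean(utils::tail(s$outcome, n) == "correct")
}

type_perf_last <- function(history, n) {
  s <- scored(history)
  if (nrow(s) < n) return(c(lick_left = NA_real_, lick_right = NA_real_))
  s <- utils::tail(s, n)
  vapply(c("lick_left", "lick_right"), function(tt) {
    k <- s$trial_type == tt
    if (!any(k)) NA_real_ else mean(s$outcome[k] == "correct")
  }, numeric(1))
}

#' Advance the training stage
#'
#' Directional licking advances to discrimination at >= 70% correct over the
#' last 30 scored trials; discrimination advances to the delay stage at
#' >= 75%.  Within the delay stage the delay duration starts at 0.3 s and
#' increases by 0.2 s each time 70% is reached again (evaluated only once 30
#' scored trials have accrued at the current delay); training completes when
#' the delay reaches 1.3 s.  In reversal mode the delay stage is skipped and
#' the protocol remains in discrimination.
#'
#' @param state A [task_state()].
#' @param history Trial history data frame (see file header).  Only the
#'   trials since the last stage/delay change are considered, which the
#'   closed-loop runner guarantees by passing `state$scored_since_change`.
#' @return The updated state.
#' @export
advance_stage <- function(state, history) {
  stopifnot(inherits(state, "task_state"))
  s <- scored(history)
  n_new <- min(nrow(s), state$scored_since_change)
  ## criteria are assessed over consecutive non-overlapping 30-trial blocks
  if (n_new < 30L || state$scored_since_change %% 30L != 0L) return(state)
  p30 <- mean(utils::tail(s$outcome, 30L) == "correct")
  if (state$stage == "directional" && p30 >= 0.70) {
    state$stage <- "discrimination"
    state$scored_since_change <- 0L
  } else if (state$stage == "discrimination" && p30 >= 0.75 &&
             !state$reversal_mode) {
    state$stage <- "delay"
    state$delay_duration <- 0.3
    state$scored_since_change <- 0L
  } else if (state$stage == "delay" && p30 >= 0.70) {
    state$delay_duration <- round(state$delay_duration + 0.2, 10)
    if (state$delay_duration >= 1.3 - 1e-9) {
      # the ramp ends when the delay reaches 1.3 s
      state$delay_duration <- 1.3
      state$stage <- "complete"
    }
    state$scored_since_change <- 0L
  }
  state
}

#' Select the next trial type
#'
#' In the directional-licking stage trial types are presented in blocks:
#' the same type repeats until three trials of it are correct, then the type
#' switches.  In later stages the type is drawn from
#' `state$trial_type_probabilities`, overridden by an active forced-repeat
#' assist (same type until two correct).
#'
#' @param state A [task_state()].
#' @return List with the chosen `trial_type` and the updated state.
#' @export
select_trial_type <- function(state) {
  stopifnot(inherits(state, "task_state"))
  if (state$stage == "directional")
    return(list(trial_type = state$block_type, state = state))
  if (!is.na(state$forced_repeat_type))
    return(list(trial_type = state$forced_repeat_type, state = state))
  tt <- sample(c("lick_left", "lick_right"), 1L,
               prob = state$trial_type_probabilities)
  list(trial_type = tt, state = state)
}

#' Record a finished trial into the scheduler state
#'
#' Updates the directional block counter (switch after three correct),
#' the forced-repeat counter (cleared after two correct), and the
#' scored-trial counter used by criterion windows.
#'
#' @param state A [task_state()].
#' @param trial_type,outcome The finished trial.
#' @return The updated state.
#' @export
record_trial_result <- function(state, trial_type, outcome) {
  if (outcome != "ignore")
    state$scored_since_change <- state$scored_since_change + 1L
  if (state$stage == "directional" && trial_type == state$block_type) {
    if (outcome == "correct") {
      state$block_correct <- state$block_correct + 1L
      if (state$block_correct >= 3L) {
        state$block_type <- other_type(state$block_type)
        state$block_correct <- 0L
      }
    }
  }
  if (!is.na(state$forced_repeat_type) &&
      trial_type == state$forced_repeat_type) {
    if (outcome == "correct") {
      state$forced_repeat_correct <- state$forced_repeat_correct + 1L
      if (state$forced_repeat_correct >= 2L) {
        state$forced_repeat_type <- NA_character_
        state$forced_repeat_correct <- 0L
      }
    }
  }
  state
}

other_type <- function(tt) if (tt == "lick_left") "lick_right" else "lick_left"

#' Evaluate the auto-assist programs
#'
#' Four programs counter idiosyncratic biases: (1) if the performance
#' difference between trial types exceeds 30 points in the last 50 trials or
#' 80 points in the last 20, the lickport moves so the non-preferred spout is
#' closer; (2) five consecutive errors in one trial type trigger a free
#' water reward on that type's spout in its next trial; (3) the worse
#' trial type over the last 30 trials is presented more frequently,
#' p(worse) = 0.5 + 0.5 min(0.3, Δaccuracy), capped at 0.8; (4) three
#' consecutive errors in one type force that type to repeat until two
#' correct.  Windows use scored trials and are inactive until full; ignore
#' trials break consecutive-error runs.
#'
#' @param state A [task_state()].
#' @param history Trial history data frame.
#' @return List with `actions` (character subset of `move_lickport`,
#'   `free_reward`, `reweight`, `forced_repeat`), `free_reward_type`
#'   (trial type owed a free reward or `NA`) and the updated state.
#' @export
evaluate_autoassist <- function(state, history) {
  stopifnot(inherits(state, "task_state"))
  actions <- character(0)
  free_type <- NA_character_

  p50 <- type_perf_last(history, 50L)
  p20 <- type_perf_last(history, 20L)
  biased <- (all(is.finite(p50)) && abs(p50[1] - p50[2]) > 0.30) ||
    (all(is.finite(p20)) && abs(p20[1] - p20[2]) > 0.80)
  if (biased) {
    actions <- c(actions, "move_lickport")
    ref <- if (all(is.finite(p50)) && abs(p50[1] - p50[2]) > 0.30) p50 else p20
    # worse-performing side's spout moves closer: + offset favors right spout
    step <- if (ref["lick_left"] < ref["lick_right"]) -1 else 1
    state$lickport_offset <- max(-3, min(3, state$lickport_offset + step))
  } else if (state$lickport_offset != 0) {
    state$lickport_offset <- state$lickport_offset -
      sign(state$lickport_offset)  # bias cleared: walk back to center
  }

  s <- scored(history)
  for (tt in c("lick_left", "lick_right")) {
    k <- which(s$trial_type == tt)
    if (length(k) >= 5L) {
      last5 <- utils::tail(k, 5L)
      # consecutive in scored time: no correct of this type in between
      if (all(s$outcome[last5] == "error")) {
        actions <- c(actions, "free_reward")
        free_type <- tt
      }
    }
    if (length(k) >= 3L && is.na(state$forced_repeat_type)) {
      if (all(s$outcome[utils::tail(k, 3L)] == "error")) {
        actions <- c(actions, "forced_repeat")
        state$forced_repeat_type <- tt
        state$forced_repeat_correct <- 0L
      }
    }
  }

  p30 <- type_perf_last(history, 30L)
  if (all(is.finite(p30)) && state$stage != "directional") {
    d <- abs(p30[1] - p30[2])
    if (d > 0) {
      worse <- if (p30["lick_left"] < p30["lick_right"]) "lick_left"
      else "lick_right"
      p_worse <- min(0.5 + 0.5 * min(0.3, d), 0.8)
      probs <- c(lick_left = 1 - p_worse, lick_right = 1 - p_worse)
      probs[worse] <- p_worse
      if (d > 0.05) actions <- c(actions, "reweight")
      state$trial_type_probabilities <- probs
    } else {
      state$trial_type_probabilities <- c(lick_left = 0.5, lick_right = 0.5)
    }
  }

  list(actions = unique(actions), free_reward_type = free_type, state = state)
}

#' Check and apply contingency reversal
#'
#' In reversal mode, once performance exceeds 80% correct over the last 100
#' scored trials (strictly, and only counting trials since the last flip),
#' the stimulus-to-lick-direction mapping is reversed and the criterion
#' window restarts.
#'
#' @param state A [task_state()] with `reversal_mode = TRUE`.
#' @param history Trial history data frame.
#' @return The updated state (`contingency` flipped and `n_reversals`
#'   incremented when the criterion is met).
#' @export
check_contingency_reversal <- function(state, history) {
  stopifnot(inherits(state, "task_state"))
  if (!state$reversal_mode || state$stage == "directional") return(state)
  s <- scored(history)
  if (min(nrow(s), state$scored_since_change) < 100L ||
      state$scored_since_change %% 100L != 0L) return(state)
  if (mean(utils::tail(s$outcome, 100L) == "correct") > 0.80) {
    state$contingency <- if (state$contingency == "standard") "reversed"
    else "standard"
    state$n_reversals <- state$n_reversals + 1L
    state$scored_since_change <- 0L
  }
  state
}

#' Schedule photostimulation for a trial
#'
#' During the optogenetics protocol a random subset of trials (probability
#' `p`, nominally 10%) receives a photostimulus, with the epoch uniform over
#' the enabled epochs and the intensity uniform over the configured set.
#' The masking flash is present on every trial regardless.
#'
#' @param enabled_epochs Character subset of `c("sample","delay","response")`.
#' @param intensity_set Numeric vector of intensities (mW/mm^2).
#' @param p Probability of photostimulation.
#' @return A [photostim_assignment()] or `NULL`.
#' @export
assign_photostim <- function(enabled_epochs = c("sample", "delay", "response"),
                             intensity_set = c(0.3, 1.5, 3.5),
                             p = 0.10) {
  if (length(intensity_set) == 0L)
    stop("intensity_set must not be empty")
  if (stats::runif(1) >= p) return(NULL)
  epoch <- if (length(enabled_epochs) == 1L) enabled_epochs
  else sample(enabled_epochs, 1L)
  intensity <- if (length(intensity_set) == 1L) intensity_set
  else sample(intensity_set, 1L)
  photostim_assignment(epoch, intensity)
}
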