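# Closed-loop home-cage simulation: the mouse agent drives the headport
# entry, head-fixation and task-training state machines, producing trial,
# fixation and milestone logs that feed the analysis stack.

#' Simulate a full home-cage run
#'
#' Runs the agent through headport-entry luring, head-fixation training
#' (3 to 30 s duration ramp with adaptive release thresholds), and the
#' staged task protocol (directional licking, discrimination, delay), with
#' auto-assist programs active during task training.  After task training
#' completes, the fixation duration extends from 30 to 60 s; an optional
#' optogenetic testing phase then tags ~10% of trials with photostimulation
#' while the agent's learning schedules are frozen.  In reversal mode the
#' delay stage is skipped and the contingency flips at each >80%/100-trial
#' criterion.
#'
#' @param params An [agent_params()].
#' @param seed Integer seed; all randomness derives from it.
#' @param max_trials Trial budget for the run.
#' @param reversal_mode Logical; contingency-reversal training.
#' @param target_reversals Stop after this many flips (reversal mode).
#' @param n_trials_after_complete Extra (non-opto) trials to run after the
#'   task protocol completes.
#' @param opto Optional list with `enabled_epochs`, `intensity_set`, `p`
#'   and `n_trials`: runs an optogenetic testing phase after training.
#' @return A list of class `homecage_run` with `trials` (data frame),
#'   `fixations` (data frame), `milestones`, the final `task`, `headfix`
#'   and `agent` states, and `params`.
#' @export
simulate_homecage <- function(params = agent_params(),
                              seed = 1L,
                              max_trials = 20000L,
                              reversal_mode = FALSE,
                              target_reversals = 3L,
                              n_trials_after_complete = 0L,
                              opto = NULL) {
  set.seed(seed)
  agent <- agent_state(params)
  hstate <- headfix_state()
  tstate <- task_state(reversal_mode = reversal_mode)
  wall <- 0
  fx_start <- numeric(0); fx_end <- numeric(0); fx_sched <- numeric(0)
  fx_type <- character(0); fx_ntr <- integer(0); fx_last <- character(0)
  add_fix <- function(start, end, sched, type, ntr, last) {
    fx_start[n_fix] <<- start; fx_end[n_fix] <<- end
    fx_sched[n_fix] <<- sched; fx_type[n_fix] <<- type
    fx_ntr[n_fix] <<- ntr; fx_last[n_fix] <<- last
  }
  milestones <- list(seed = seed)

  ## ---- Phase 1: headport entry -------------------------------------------
  while (hstate$subprotocol == "headport_entry") {
    if (hstate$lickport_distance < HEADPORT_MAX_DISTANCE) {
      hstate <- step_headport_entry(hstate, "rewarded_lick")
      wall <- wall + stats::rexp(1, 1 / 30)   # rewarded licks accrue slowly
    } else {
      hstate <- step_headport_entry(hstate, "switch_trigger")
      wall <- wall + stats::rexp(1, 1 / 120)
    }
  }
  milestones$headport_entry_end_s <- wall

  ## ---- Phase 2: head-fixation training -----------------------------------
  n_fix <- 0L
  while (hstate$subprotocol == "head_fixation") {
    sched <- hstate$fixation_duration
    rel <- sample_release(params, sched, hstate$release_thresholds)
    hstate <- step_fixation_training(hstate, rel$type)
    n_fix <- n_fix + 1L
    add_fix(wall, wall + rel$time, sched, rel$type, 0L, NA_character_)
    wall <- wall + rel$time + sample_engagement(params, wall)
  }
  milestones$fixation_training_fixations <- n_fix
  milestones$fixation_training_end_s <- wall
  hstate$phase <- "training_done"   # duration stays at 30 s during task

  ## ---- Phase 3: task training (+ extension, + optional opto) -------------
  n <- 0L
  cap <- max_trials
  tt_type <- character(cap); tt_pole <- integer(cap)
  tt_choice <- character(cap); tt_outcome <- character(cap)
  tt_stage <- character(cap); tt_conting <- character(cap)
  tt_delay <- numeric(cap); tt_early <- integer(cap)
  tt_stim_epoch <- character(cap); tt_stim_int <- numeric(cap)
  tt_fix <- integer(cap); tt_start <- numeric(cap)
  tt_flags <- character(cap)
  scored_correct <- integer(cap)   # 1/0 per scored trial
  scored_stage_ok <- logical(cap)  # scored trial at/after discrimination
  m_sc <- 0L
  hist_type <- character(cap); hist_outcome <- character(cap)

  pending_free <- NA_character_
  opto_trials_done <- 0L
  post_complete_done <- 0L
  criterion_trial <- NA_integer_
  complete_trial <- NA_integer_
  stage_seen <- c(directional = 0L)
  last_outcome_in_fix <- NA_character_
  extension_started <- FALSE

  window_df <- function(k) {
    if (n == 0L) return(data.frame(trial_type = character(0),
                                   outcome = character(0)))
    idx <- seq.int(max(1L, n - k + 1L), n)
    data.frame(trial_type = hist_type[idx], outcome = hist_outcome[idx])
  }

  done <- function() {
    if (n >= max_trials) return(TRUE)
    if (reversal_mode) return(tstate$n_reversals >= target_reversals)
    if (tstate$stage != "complete") return(FALSE)
    if (!is.null(opto)) return(opto_trials_done >= opto$n_trials)
    post_complete_done >= n_trials_after_complete
  }

  while (!done()) {
    ## one head-fixation holding a run of trials
    sched <- hstate$fixation_duration
    rel <- sample_release(params, sched, hstate$release_thresholds)
    fix_start <- wall
    elapsed <- 0
    n_in_fix <- 0L
    last_outcome_in_fix <- NA_character_

    while (elapsed < rel$time && !done()) {
      n <- n + 1L
      stage <- tstate$stage
      opto_phase <- !is.null(opto) && stage == "complete"
      in_training <- stage %in% c("directional", "discrimination", "delay")

      ## scheduling + assists
      flags <- character(0)
      free_this <- FALSE
      if (in_training && stage != "directional") {
        aa <- evaluate_autoassist(tstate, window_df(120L))
        tstate <- aa$state
        if (!is.na(aa$free_reward_type)) pending_free <- aa$free_reward_type
        flags <- aa$actions
      }
      sel <- select_trial_type(tstate)
      tstate <- sel$state
      trial_type <- sel$trial_type
      if (!is.na(pending_free) && trial_type == pending_free) {
        free_this <- TRUE
        pending_free <- NA_character_
        flags <- unique(c(flags, "free_reward"))
      }
      stim <- NULL
      if (opto_phase) {
        agent$frozen <- TRUE
        stim <- assign_photostim(opto$enabled_epochs, opto$intensity_set,
                                 p = if (is.null(opto$p)) 0.10 else opto$p)
      }

      ## trial configuration by stage
      delay <- switch(stage, directional = 0.2, discrimination = 0.2,
                      tstate$delay_duration)
      if (stage == "complete" && !reversal_mode) delay <- 1.3
      if (reversal_mode && stage != "directional") delay <- 0.2
      cfg <- trial_config(delay_duration = delay,
                          error_timeout = if (stage == "directional") 2 else 4,
                          enforce_delay = stage %in% c("delay", "complete") &&
                            !reversal_mode)

      ## agent behavior
      pole_chr <- pole_position(trial_type, tstate$contingency)
      pole <- if (pole_chr == "anterior") 1 else -1
      beh <- sample_trial_behavior(agent, pole, stage = stage, stim = stim,
                                   free_reward = free_this,
                                   trial_type = trial_type,
                                   lickport_offset = tstate$lickport_offset,
                                   delay_duration = delay)
      rec <- run_trial(cfg, beh, trial_type, stage = stage,
                       contingency = tstate$contingency, stim = stim,
                       trial_index = n)

      ## bookkeeping
      hist_type[n] <- trial_type
      hist_outcome[n] <- rec$outcome
      tstate <- record_trial_result(tstate, trial_type, rec$outcome)
      if (in_training) {
        tstate <- advance_stage(tstate, window_df(40L))
        if (reversal_mode)
          tstate <- check_contingency_reversal(tstate, window_df(120L))
      }
      agent <- update_learning_state(agent, pole, rec$choice, rec$outcome,
                                     reversal_mode = reversal_mode &&
                                       tstate$stage != "directional")

      if (rec$outcome != "ignore") {
        m_sc <- m_sc + 1L
        scored_correct[m_sc] <- as.integer(rec$outcome == "correct")
        scored_stage_ok[m_sc] <- stage != "directional"
        last_outcome_in_fix <- rec$outcome
        if (is.na(criterion_trial) && m_sc >= 200L && scored_stage_ok[m_sc] &&
            mean(scored_correct[(m_sc - 199L):m_sc]) >= 0.70)
          criterion_trial <- n
      }
      if (!(tstate$stage %in% names(stage_seen))) {
        stage_seen[tstate$stage] <- n
        if (tstate$stage == "complete") complete_trial <- n
      }
      if (tstate$stage == "complete") {
        if (opto_phase) opto_trials_done <- opto_trials_done + 1L
        else if (is.null(opto)) post_complete_done <- post_complete_done + 1L
        if (!extension_started) {
          hstate$phase <- "extension"
          extension_started <- TRUE
        }
      }

      tt_type[n] <- trial_type; tt_pole[n] <- pole
      tt_choice[n] <- rec$choice; tt_outcome[n] <- rec$outcome
      tt_stage[n] <- stage; tt_conting[n] <- rec$contingency
      tt_delay[n] <- delay; tt_early[n] <- rec$early_lick_count
      tt_stim_epoch[n] <- if (is.null(stim)) NA_character_ else stim$epoch
      tt_stim_int[n] <- if (is.null(stim)) NA_real_ else stim$intensity
      tt_fix[n] <- n_fix + 1L; tt_start[n] <- wall + elapsed
      tt_flags[n] <- paste(flags, collapse = ";")
      elapsed <- elapsed + rec$trial_duration
      n_in_fix <- n_in_fix + 1L
    }

    rel_time <- if (rel$type == "time_up") max(rel$time, elapsed) else rel$time
    hstate <- step_fixation_training(hstate, rel$type)
    n_fix <- n_fix + 1L
    add_fix(fix_start, fix_start + rel_time, sched, rel$type, n_in_fix,
            last_outcome_in_fix)
    wall <- fix_start + rel_time +
      sample_engagement(params, fix_start + rel_time, last_outcome_in_fix)
  }

  trials <- data.frame(trial_index = seq_len(n),
                       fixation_id = tt_fix[seq_len(n)],
                       start_time = tt_start[seq_len(n)],
                       stage = tt_stage[seq_len(n)],
                       trial_type = tt_type[seq_len(n)],
                       pole = tt_pole[seq_len(n)],
                       contingency = tt_conting[seq_len(n)],
                       delay_duration = tt_delay[seq_len(n)],
                       choice = tt_choice[seq_len(n)],
                       outcome = tt_outcome[seq_len(n)],
                       early_lick_count = tt_early[seq_len(n)],
                       stim_epoch = tt_stim_epoch[seq_len(n)],
                       stim_intensity = tt_stim_int[seq_len(n)],
                       autoassist = tt_flags[seq_len(n)])
  milestones$stage_trials <- stage_seen
  milestones$criterion_trial <- criterion_trial
  milestones$complete_trial <- complete_trial
  milestones$n_reversals <- tstate$n_reversals
  milestones$n_trials <- n

  fixations <- data.frame(start_time = fx_start, end_time = fx_end,
                          scheduled_duration = fx_sched,
                          release_type = fx_type, n_trials = fx_ntr,
                          last_outcome = fx_last)
  structure(list(trials = trials,
                 fixations = fixations,
                 milestones = milestones,
                 task = tstate, headfix = hstate, agent = agent,
                 params = params),
            class = "homecage_run")
}

#' @export
print.homecage_run <- function(x, ...) {
  m <- x$milestones
  cat("homecage_run:", m$n_trials, "trials,",
      nrow(x$fixations), "fixations\n")
  cat("  stage reached:", x$task$stage,
      if (x$task$reversal_mode) sprintf("(%d reversals)", m$n_reversals)
      else "", "\n")
  if (!is.na(m$criterion_trial))
    cat("  70% criterion (200-trial window) at trial", m$criterion_trial, "\n")
  invisible(x)
}
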