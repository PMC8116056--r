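# Generative simulated mouse.  The agent closes the loop with the protocol
# state machines and doubles as the package's synthetic-data generator.
#
# Choice policy: P(left) = logistic(v * pole + w_hist * A1 + w_wsls * A1*R1
# + bias + assist/photostim shifts), on +/-1-coded inputs (pole +1 =
# anterior, choice +1 = left, reward +1 = rewarded), with a lapse mixture.
# Over training the stimulus weight v rises along a sigmoid schedule while
# the choice-history and win-stay-lose-switch weights decay, reproducing the
# strategy progression the analysis stack is designed to detect.  In
# contingency-reversal mode v is instead updated by a reward-driven delta
# rule so the agent can re-learn a flipped stimulus-response mapping.

#' Agent parameters
#'
#' Defaults define the reference simulated mouse used throughout the
#' package's tests and examples.
#'
#' @param w_stim_max Asymptotic stimulus weight (logit units).
#' @param learn_midpoint,learn_scale Midpoint (trials) and scale (trials) of
#'   the sigmoid learning schedule.
#' @param w_hist_start,w_hist_end Perseveration (previous-choice) weight at
#'   the start and end of learning.
#' @param w_wsls_start,w_wsls_end Win-stay-lose-switch weight at the start
#'   and end of learning.
#' @param bias Constant left bias (logit units).
#' @param lapse_rate Probability of a uniform-random choice.
#' @param early_lick_rate0 Expected early licks per trial at the start of
#'   training; decays exponentially with time constant `early_lick_decay`
#'   (trials).
#' @param early_lick_decay See `early_lick_rate0`.
#' @param ignore_rate Probability of withholding the response lick.
#' @param free_reward_follow Probability that a free water reward pulls the
#'   next choice to the rewarded spout.
#' @param lickport_bias_per_mm Logit shift toward the closer spout per mm of
#'   lickport offset.
#' @param within_bout_scale Within-bout inter-fixation gap scale (seconds).
#' @param between_bout_mean Between-bout interval mean (seconds).
#' @param p_within_bout Probability the next fixation continues the bout.
#' @param error_ifi_multiplier Multiplier on the inter-fixation interval
#'   after a fixation whose last scored trial was an error (> 1 mirrors the
#'   post-error disengagement seen in home-cage data).
#' @param dark_cycle_preference Fraction of bout starts placed in the dark
#'   cycle.
#' @param struggle_rate Struggle excursions per second during fixation.
#' @param struggle_amp_mean Mean excursion amplitude (grams).
#' @param resting_load Mean on-platform load during fixation (grams).
#' @param escape_rate Probability of withdrawing before the pistons clamp.
#' @param reversal_learning_rate Delta-rule rate for reversal mode.
#' @param photostim_effects Named list mapping an epoch
#'   (`"sample"`/`"delay"`/`"response"`) to a list with optional
#'   `bias_shift` (additive logit shift, + = leftward) and `stim_atten`
#'   (multiplier in [0,1] on the stimulus weight) applied on photostim
#'   trials of that epoch.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(w_stim_max = 2.5,
                         learn_midpoint = 8000,
                         learn_scale = 1500,
                         w_hist_start = 0.5,
                         w_hist_end = 0.1,
                         w_wsls_start = 0.9,
                         w_wsls_end = 0,
                         bias = 0,
                         lapse_rate = 0.05,
                         early_lick_rate0 = 0.5,
                         early_lick_decay = 3000,
                         ignore_rate = 0.03,
                         free_reward_follow = 0.9,
                         lickport_bias_per_mm = 0.2,
                         within_bout_scale = 1,
                         between_bout_mean = 2400,
                         p_within_bout = 0.8,
                         error_ifi_multiplier = 1.5,
                         dark_cycle_preference = 0.67,
                         struggle_rate = 0.08,
                         struggle_amp_mean = 15,
                         resting_load = 5,
                         escape_rate = 0.05,
                         reversal_learning_rate = 0.05,
                         photostim_effects = list()) {
  p <- as.list(environment())
  probs <- c(p$lapse_rate, p$ignore_rate, p$free_reward_follow,
             p$p_within_bout, p$dark_cycle_preference, p$escape_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$error_ifi_multiplier <= 0) stop("error_ifi_multiplier must be > 0")
  structure(p, class = "agent_params")
}

#' Initialise agent state
#'
#' @param params An [agent_params()].
#' @return An object of class `agent_state` holding the policy weights, the
#'   trial clock `t`, and the last choice/reward.
#' @export
agent_state <- function(params = agent_params()) {
  st <- list(params = params, t = 0L,
             v_stim = schedule_weight(0, 0, params$w_stim_max,
                                      params$learn_midpoint,
                                      params$learn_scale),
             w_hist = params$w_hist_start,
             w_wsls = params$w_wsls_start,
             last_choice = 0,   # +/-1; 0 before the first scored trial
             last_reward = 0,
             frozen = FALSE)    # schedules halt during optogenetic testing
  structure(st, class = "agent_state")
}

# Sigmoid schedule from `from` to `to` with midpoint m and scale s.
schedule_weight <- function(t, from, to, m, s) {
  from + (to - from) * stats::plogis((t - m) / s)
}

#' Sample one trial of behavior from the agent
#'
#' @param agent An [agent_state()].
#' @param pole `+1` (anterior) or `-1` (posterior).
#' @param stage Training stage (early licks are emitted in sample/delay).
#' @param stim Optional [photostim_assignment()]; applies the configured
#'   photostim effect for its epoch.
#' @param free_reward Logical; a free reward was delivered on this trial's
#'   rewarded spout.
#' @param trial_type This trial's rewarded direction (used only to honor a
#'   free reward).
#' @param lickport_offset Current lickport offset in mm.
#' @param delay_duration Current delay duration (for early-lick placement).
#' @return A `behavior` list as consumed by [run_trial()], plus the `p_left`
#'   actually used.
#' @export
sample_trial_behavior <- function(agent, pole, stage = "delay", stim = NULL,
                                  free_reward = FALSE,
                                  trial_type = "lick_left",
                                  lickport_offset = 0,
                                  delay_duration = 1.3) {
  p <- agent$params
  z <- agent$v_stim * pole + agent$w_hist * agent$last_choice +
    agent$w_wsls * agent$last_choice * agent$last_reward + p$bias
  # lickport moved toward a spout makes licking it easier (+offset = right
  # spout closer = rightward shift)
  z <- z - p$lickport_bias_per_mm * lickport_offset
  if (!is.null(stim)) {
    eff <- p$photostim_effects[[stim$epoch]]
    if (!is.null(eff)) {
      if (!is.null(eff$stim_atten)) z <- z - (1 - eff$stim_atten) *
          agent$v_stim * pole
      if (!is.null(eff$bias_shift)) z <- z + eff$bias_shift
    }
  }
  p_left <- stats::plogis(z)

  if (isTRUE(free_reward) && stats::runif(1) < p$free_reward_follow) {
    choice <- if (trial_type == "lick_left") "left" else "right"
  } else if (stats::runif(1) < p$lapse_rate) {
    choice <- sample(c("left", "right"), 1L)
  } else {
    choice <- if (stats::runif(1) < p_left) "left" else "right"
  }

  early <- NULL
  rate <- p$early_lick_rate0 * exp(-agent$t / p$early_lick_decay)
  n_early <- stats::rpois(1, rate)
  if (n_early > 0) {
    ep <- sample(c("sample", "delay"), n_early, replace = TRUE)
    off <- stats::runif(n_early, 0, 1) *
      ifelse(ep == "sample", 1.3, delay_duration)
    early <- data.frame(epoch = ep, offset = off,
                        spout = sample(c("left", "right"), n_early,
                                       replace = TRUE))
  }
  response <- if (stats::runif(1) < p$ignore_rate) NULL
  else list(latency = stats::runif(1, 0.1, 1.2), spout = choice)

  list(early = early, response = response, p_left = p_left, choice = choice)
}

#' Advance the agent's learning state after a trial
#'
#' In standard mode the weights follow their sigmoid schedules; in reversal
#' mode the stimulus weight is updated by a delta rule
#' `v <- v + alpha * (w_stim_max * r * a * pole - v)` where `r`, `a`,
#' `pole` are the +/-1-coded reward, choice and pole position, so reward
#' feedback alone can flip the learned mapping.  Schedules freeze during
#' optogenetic testing (`agent$frozen`).
#'
#' @param agent An [agent_state()].
#' @param pole,choice,outcome The finished trial (`choice` `"left"`/
#'   `"right"`/`"ignore"`).
#' @param reversal_mode Logical.
#' @return The updated agent state.
#' @export
update_learning_state <- function(agent, pole, choice, outcome,
                                  reversal_mode = FALSE) {
  p <- agent$params
  agent$t <- agent$t + 1L
  if (!agent$frozen) {
    if (reversal_mode && choice != "ignore") {
      a <- if (choice == "left") 1 else -1
      r <- if (outcome == "correct") 1 else -1
      agent$v_stim <- agent$v_stim + p$reversal_learning_rate *
        (p$w_stim_max * r * a * pole - agent$v_stim)
      agent$w_hist <- schedule_weight(agent$t, p$w_hist_start, p$w_hist_end,
                                      p$learn_midpoint, p$learn_scale)
      agent$w_wsls <- schedule_weight(agent$t, p$w_wsls_start, p$w_wsls_end,
                                      p$learn_midpoint, p$learn_scale)
    } else if (!reversal_mode) {
      agent$v_stim <- schedule_weight(agent$t, 0, p$w_stim_max,
                                      p$learn_midpoint, p$learn_scale)
      agent$w_hist <- schedule_weight(agent$t, p$w_hist_start, p$w_hist_end,
                                      p$learn_midpoint, p$learn_scale)
      agent$w_wsls <- schedule_weight(agent$t, p$w_wsls_start, p$w_wsls_end,
                                      p$learn_midpoint, p$learn_scale)
    }
  }
  if (choice != "ignore") {
    agent$last_choice <- if (choice == "left") 1 else -1
    agent$last_reward <- if (outcome == "correct") 1 else -1
  }
  agent
}

#' Sample the next inter-fixation interval
#'
#' Inter-fixation intervals are a two-component mixture: with probability
#' `p_within_bout` a short within-bout gap (exponential, ~1 s scale), else a
#' long between-bout interval (exponential).  Both components are multiplied
#' by `error_ifi_multiplier` when the previous fixation ended on an error.
#' Between-bout re-entries are placed in the dark cycle with probability
#' `dark_cycle_preference` (days are 86400 s; dark is the first half).
#'
#' @param params An [agent_params()].
#' @param wall_clock Current time (seconds from run start).
#' @param last_outcome Outcome of the last scored trial of the previous
#'   fixation (`"correct"`, `"error"`, or `NA`).
#' @return The inter-fixation interval in seconds.
#' @export
sample_engagement <- function(params, wall_clock = 0,
                              last_outcome = NA_character_) {
  mult <- if (identical(last_outcome, "error")) params$error_ifi_multiplier
  else 1
  if (stats::runif(1) < params$p_within_bout)
    return(mult * stats::rexp(1, 1 / params$within_bout_scale))
  ifi <- mult * stats::rexp(1, 1 / params$between_bout_mean)
  t_next <- wall_clock + ifi
  day_pos <- t_next %% 86400
  in_dark <- day_pos < 43200
  want_dark <- stats::runif(1) < params$dark_cycle_preference
  if (in_dark != want_dark) {
    # defer to the next preferred half-cycle
    ifi <- ifi + (43200 - day_pos %% 43200)
  }
  ifi
}

#' Sample how a head-fixation ends (analytic struggle model)
#'
#' Equivalent in distribution to generating a load trace with
#' [simulate_load_trace()] and resolving it with [resolve_release()]:
#' struggle excursions arrive as a Poisson process at `struggle_rate`; each
#' has an exponential amplitude with random sign and crosses the release
#' band `(lower, upper)` if `resting_load - amp <= lower` (downward) or
#' `resting_load + amp >= upper` (upward).
#'
#' @param params An [agent_params()].
#' @param scheduled Scheduled fixation duration (seconds).
#' @param thresholds Numeric `c(lower, upper)` grams.
#' @return List with `type` and `time` as in [resolve_release()].
#' @export
sample_release <- function(params, scheduled, thresholds) {
  if (stats::runif(1) < params$escape_rate)
    return(list(type = "escape", time = stats::runif(1, 0, 0.2)))
  lower <- thresholds[[1]]; upper <- thresholds[[2]]
  p_down <- exp(-max(0, params$resting_load - lower) /
                  params$struggle_amp_mean)
  p_up <- exp(-max(0, upper - params$resting_load) /
                params$struggle_amp_mean)
  p_cross <- 0.5 * (p_down + p_up)   # excursion sign is symmetric
  rate <- params$struggle_rate * p_cross
  if (rate > 0) {
    t_cross <- stats::rexp(1, rate)
    if (t_cross < scheduled)
      return(list(type = "self_release", time = t_cross))
  }
  list(type = "time_up", time = scheduled)
}

#' Generate trials from a fixed-weight choice policy
#'
#' A stripped-down open-loop generator: trial types are drawn i.i.d. with
#' probability `p_left_type`, and the choice follows
#' `P(left) = plogis(w_stim * S0 + w_hist * A1 + w_wsls * A1*R1 + bias)`
#' with an optional lapse mixture.  Weights are fixed (no learning), which
#' makes the generative parameters the ground truth for parameter-recovery
#' studies of the choice model.
#'
#' @param n Number of trials.
#' @param w_stim,w_hist,w_wsls,bias Policy weights (logit units).
#' @param lapse Probability of a uniform-random choice.
#' @param p_left_type Probability of a lick-left-instructing trial.
#' @return A trial data frame with columns `trial_type`, `choice`,
#'   `outcome` suitable for [build_design()].
#' @export
generate_policy_trials <- function(n, w_stim = 2, w_hist = 0.5,
                                   w_wsls = 0, bias = 0, lapse = 0,
                                   p_left_type = 0.5) {
  S <- ifelse(stats::runif(n) < p_left_type, 1, -1)
  A <- integer(n); R <- integer(n)
  a_prev <- 0; r_prev <- 0
  u_lapse <- stats::runif(n)
  u_choice <- stats::runif(n)
  u_side <- stats::runif(n)
  for (i in seq_len(n)) {
    p_left <- stats::plogis(w_stim * S[i] + w_hist * a_prev +
                              w_wsls * a_prev * r_prev + bias)
    a <- if (u_lapse[i] < lapse) {
      if (u_side[i] < 0.5) 1 else -1
    } else if (u_choice[i] < p_left) 1 else -1
    r <- if (a == S[i]) 1 else -1
    A[i] <- a; R[i] <- r
    a_prev <- a; r_prev <- r
  }
  data.frame(trial_type = ifelse(S == 1, "lick_left", "lick_right"),
             choice = ifelse(A == 1, "left", "right"),
             outcome = ifelse(R == 1, "correct", "error"))
}
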