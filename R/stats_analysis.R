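# Behavioral and electrophysiological statistics: percent-correct
# performance, the nested mouse/session/trial bootstrap for
# photostimulation effects, the 2x2 proportion test, inter-fixation
# interval analyses, and spike-rate modulation metrics.

#' Percent correct performance
#'
#' Performance is the percentage of correct choices among scored trials;
#' ignore trials are excluded.
#'
#' @param outcomes Character vector of `"correct"`/`"error"`/`"ignore"`, or
#'   a trial data frame with an `outcome` column.
#' @param by Optional factor (e.g. trial type) to split by; must align with
#'   `outcomes`.
#' @return Percent correct (scalar, or named vector when `by` is given).
#' @export
performance <- function(outcomes, by = NULL) {
  if (is.data.frame(outcomes)) {
    if (!is.null(by) && length(by) == 1L && by %in% names(outcomes))
      by <- outcomes[[by]]
    outcomes <- outcomes$outcome
  }
  if (!is.null(by)) {
    keep <- outcomes != "ignore"
    return(tapply(outcomes[keep], by[keep],
                  function(o) 100 * mean(o == "correct")))
  }
  sc <- outcomes[outcomes != "ignore"]
  if (length(sc) == 0L) stop("no scored trials: performance undefined")
  100 * mean(sc == "correct")
}

#' Nested (mouse/session/trial) bootstrap for a performance change
#'
#' Quantifies a condition effect (e.g. photostimulation vs control) on
#' performance.  The observed effect is the within-mouse performance
#' difference (condition minus reference), averaged unweighted across mice.
#' Each bootstrap round resamples mice with replacement, then sessions
#' within each resampled mouse, then trials within each resampled session,
#' and recomputes the effect.  The one-tailed p-value is the fraction of
#' resampled effects whose sign is opposite to the observed effect.
#'
#' @param data Data frame with columns `mouse`, `session`, `condition`, and
#'   `outcome` (`"correct"`/`"error"`/`"ignore"`) or logical `correct`.
#' @param conditions Length-2 character vector `c(reference, test)`; the
#'   effect is test minus reference (percentage points).
#' @param n_resamples Number of bootstrap rounds.
#' @return An object of class `bootstrap_result`: `observed_effect`,
#'   `p_one_tailed`, `n_resamples`, `resamples` (the full distribution),
#'   and `summary` (mean, sd, quantiles).
#' @export
nested_bootstrap_effect <- function(data, conditions = c("control", "stim"),
                                    n_resamples = 10000L) {
  stopifnot(all(c("mouse", "session", "condition") %in% names(data)))
  if (!"correct" %in% names(data)) {
    data <- data[data$outcome != "ignore", , drop = FALSE]
    data$correct <- data$outcome == "correct"
  }
  data <- data[data$condition %in% conditions, , drop = FALSE]

  ## per-(mouse, session) category counts:
  ## ref-correct, ref-error, test-correct, test-error
  key <- interaction(data$mouse, data$session, drop = TRUE)
  cell <- function(cond, corr)
    tapply((data$condition == cond) & (data$correct == corr), key, sum)
  counts <- cbind(rc = cell(conditions[1], TRUE),
                  re = cell(conditions[1], FALSE),
                  tc = cell(conditions[2], TRUE),
                  te = cell(conditions[2], FALSE))
  counts[is.na(counts)] <- 0
  ## recover each session row's mouse by matching the interaction key
  sess_mouse <- vapply(rownames(counts), function(k) {
    as.character(data$mouse[match(k, as.character(key))])
  }, character(1))

  mice <- unique(sess_mouse)
  ## drop mice lacking either condition
  ok <- vapply(mice, function(m) {
    cm <- counts[sess_mouse == m, , drop = FALSE]
    sum(cm[, "rc"] + cm[, "re"]) > 0 && sum(cm[, "tc"] + cm[, "te"]) > 0
  }, logical(1))
  if (any(!ok)) {
    warning("dropping mice lacking one condition: ",
            paste(mice[!ok], collapse = ", "))
    mice <- mice[ok]
  }
  if (length(mice) == 0L) stop("no mouse has both conditions")
  by_mouse <- lapply(mice, function(m)
    counts[sess_mouse == m, , drop = FALSE])
  names(by_mouse) <- mice

  effect_from <- function(cnt) {
    ref_n <- cnt["rc"] + cnt["re"]; tst_n <- cnt["tc"] + cnt["te"]
    if (ref_n == 0 || tst_n == 0) return(NA_real_)
    100 * (cnt["tc"] / tst_n - cnt["rc"] / ref_n)
  }
  observed <- mean(vapply(by_mouse, function(cm)
    effect_from(colSums(cm)), numeric(1)), na.rm = TRUE)

  boot <- numeric(n_resamples)
  n_m <- length(mice)
  for (b in seq_len(n_resamples)) {
    eff <- numeric(n_m)
    picked <- sample.int(n_m, n_m, replace = TRUE)
    for (j in seq_along(picked)) {
      cm <- by_mouse[[picked[j]]]
      n_s <- nrow(cm)
      srows <- if (n_s == 1L) 1L else sample.int(n_s, n_s, replace = TRUE)
      tot <- c(rc = 0, re = 0, tc = 0, te = 0)
      for (s in srows) {
        cs <- cm[s, ]
        n_tr <- sum(cs)
        if (n_tr == 0) next
        ## trial resample within session: multinomial over the four cells
        tot <- tot + drop(stats::rmultinom(1L, n_tr, cs / n_tr))
      }
      eff[j] <- effect_from(tot)
    }
    boot[b] <- mean(eff, na.rm = TRUE)
  }

  p <- if (observed >= 0) mean(boot < 0) else mean(boot > 0)
  structure(list(observed_effect = observed,
                 p_one_tailed = p,
                 n_resamples = n_resamples,
                 resamples = boot,
                 summary = c(mean = mean(boot), sd = stats::sd(boot),
                             stats::quantile(boot, c(0.025, 0.5, 0.975)))),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("nested bootstrap: effect %+.2f points, one-tailed p = %.4f (%d resamples)\n",
              x$observed_effect, x$p_one_tailed, x$n_resamples))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' One-degree-of-freedom Pearson test without continuity correction, as
#' used for comparing training success proportions between groups.
#'
#' @param tab 2x2 matrix of counts (rows = groups, columns =
#'   success/failure).
#' @return The p-value.
#' @export
chisq_proportions <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero margin")
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
}

#' Inter-fixation intervals split by preceding outcome
#'
#' The inter-fixation interval (IFI) is the time between a head-fixation
#' release and the next head-fixation.  Each IFI is classified by the
#' outcome of the last scored trial in the preceding fixation; fixations
#' with no scored trial leave their following IFI unclassified.
#'
#' @param fixations Data frame with columns `start_time`, `end_time`, and
#'   `last_outcome` (as produced by [simulate_homecage()]).
#' @return Data frame with one row per outcome class: `outcome`,
#'   `mean_ifi`, `n`.
#' @export
ifi_by_outcome <- function(fixations) {
  stopifnot(nrow(fixations) >= 2L)
  ord <- order(fixations$start_time)
  fixations <- fixations[ord, , drop = FALSE]
  ifi <- fixations$start_time[-1] - fixations$end_time[-nrow(fixations)]
  prev_outcome <- fixations$last_outcome[-nrow(fixations)]
  keep <- !is.na(prev_outcome)
  agg <- tapply(ifi[keep], prev_outcome[keep], mean)
  data.frame(outcome = names(agg),
             mean_ifi = as.numeric(agg),
             n = as.integer(table(prev_outcome[keep])[names(agg)]),
             row.names = NULL)
}

#' Classify a unit and quantify its photostimulation modulation
#'
#' Units with trough-to-peak spike width strictly below 0.55 ms are putative
#' fast-spiking (FS) neurons; all others are putative pyramidal neurons.
#' Per intensity, spike rates during photostimulation are compared with the
#' 500 ms pre-stimulus baseline by a paired two-tailed t-test across sweeps,
#' and the relative firing rate is the mean stimulation rate divided by the
#' mean baseline rate (undefined and flagged when the baseline rate is 0).
#'
#' @param sweeps Data frame for one unit with columns `intensity`,
#'   `baseline_count`, `stim_count`, and optionally `sweep`.
#' @param spike_width_ms Trough-to-peak width of the mean waveform (ms).
#' @param baseline_dur,stim_dur Window durations in seconds (0.5 and 1.3).
#' @param fs_threshold FS classification threshold (ms).
#' @return An object of class `unit_modulation`: `cell_class`,
#'   `spike_width_ms`, and a data frame `modulation` with per-intensity
#'   `baseline_rate`, `stim_rate`, `relative_rate`, `p_value`, `n_sweeps`.
#' @export
classify_unit_and_modulation <- function(sweeps, spike_width_ms,
                                         baseline_dur = 0.5, stim_dur = 1.3,
                                         fs_threshold = 0.55) {
  stopifnot(all(c("intensity", "baseline_count", "stim_count") %in%
                  names(sweeps)))
  cell_class <- if (spike_width_ms < fs_threshold) "FS" else "pyramidal"
  mod <- do.call(rbind, lapply(split(sweeps, sweeps$intensity), function(s) {
    base_rate <- s$baseline_count / baseline_dur
    stim_rate <- s$stim_count / stim_dur
    b <- mean(base_rate); st <- mean(stim_rate)
    p <- if (nrow(s) >= 2L && stats::sd(stim_rate - base_rate) > 0)
      stats::t.test(stim_rate, base_rate, paired = TRUE)$p.value
    else NA_real_
    data.frame(intensity = s$intensity[1], baseline_rate = b,
               stim_rate = st,
               relative_rate = if (b > 0) st / b else NA_real_,
               p_value = p, n_sweeps = nrow(s))
  }))
  rownames(mod) <- NULL
  structure(list(cell_class = cell_class,
                 spike_width_ms = spike_width_ms,
                 baseline_undefined = any(mod$baseline_rate == 0),
                 modulation = mod),
            class = "unit_modulation")
}

#' @export
print.unit_modulation <- function(x, ...) {
  cat(sprintf("unit: %s (width %.2f ms)\n", x$cell_class, x$spike_width_ms))
  print(x$modulation, digits = 3)
  invisible(x)
}

#' Assemble grouped trials from simulated optogenetic runs
#'
#' Builds the mouse/session/condition table consumed by
#' [nested_bootstrap_effect()] from one or more closed-loop runs with an
#' optogenetic testing phase.  Each simulated day (dark + light cycle) is
#' one session.  Control trials are unstimulated trials of the testing
#' phase; stimulation trials are those tagged with the requested epoch.
#'
#' @param runs A named list of `homecage_run` objects (names = mouse ids),
#'   or a single run.
#' @param epoch Photostimulation epoch to extract (`"sample"`, `"delay"`,
#'   `"response"`).
#' @param trial_types Optional trial-type filter (e.g. `"lick_right"`).
#' @return Data frame with columns `mouse`, `session`, `condition`
#'   (`"control"`/`"stim"`), `trial_type`, `outcome`.
#' @export
opto_grouped_trials <- function(runs, epoch = "delay", trial_types = NULL) {
  if (inherits(runs, "homecage_run")) runs <- list(mouse1 = runs)
  if (is.null(names(runs))) names(runs) <- paste0("mouse", seq_along(runs))
  do.call(rbind, lapply(names(runs), function(id) {
    tr <- runs[[id]]$trials
    tr <- tr[tr$stage == "complete" & tr$outcome != "ignore", , drop = FALSE]
    keep <- is.na(tr$stim_epoch) | tr$stim_epoch == epoch
    tr <- tr[keep, , drop = FALSE]
    if (!is.null(trial_types))
      tr <- tr[tr$trial_type %in% trial_types, , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    data.frame(mouse = id,
               session = floor(tr$start_time / 86400) + 1,
               condition = ifelse(is.na(tr$stim_epoch), "control", "stim"),
               trial_type = tr$trial_type,
               outcome = tr$outcome)
  }))
}
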