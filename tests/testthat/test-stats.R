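test_that("performance is percent correct among scored trials", {
  expect_equal(performance(c(rep("correct", 7), rep("error", 3))), 70)
  expect_equal(performance(c(rep("correct", 5), rep("error", 5),
                             rep("ignore", 4))), 50)
  expect_error(performance(rep("ignore", 3)), "undefined")
  by_type <- performance(data.frame(outcome = c("correct", "error",
                                                "correct", "correct")),
                         by = c("L", "L", "R", "R"))
  expect_equal(unname(by_type["L"]), 50)
  expect_equal(unname(by_type["R"]), 100)
})

test_that("chi-square equals the closed form on random 2x2 tables", {
  set.seed(1)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    x2 <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chisq_proportions(tab),
                 pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_equal(chisq_proportions(matrix(c(50, 50, 50, 50), 2)), 1)
  expect_lt(abs(chisq_proportions(matrix(c(10, 0, 0, 10), 2)) - 7.7e-6),
            1e-6)
  expect_error(chisq_proportions(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("training-success proportions reproduce the published comparison", {
  # 64/70 manual vs 32/37 home-cage successes
  tab <- matrix(c(64, 70 - 64, 32, 37 - 32), nrow = 2, byrow = TRUE)
  expect_equal(round(chisq_proportions(tab), 2), 0.42)
})

nested_null_data <- function(n_mice = 3, n_sessions = 2, n_trials = 120,
                             p_ctrl = 0.8, p_stim = NULL, frac_stim = 0.3) {
  if (is.null(p_stim)) p_stim <- p_ctrl
  do.call(rbind, lapply(seq_len(n_mice), function(m) {
    do.call(rbind, lapply(seq_len(n_sessions), function(s) {
      cond <- ifelse(runif(n_trials) < frac_stim, "stim", "control")
      p <- ifelse(cond == "stim", p_stim, p_ctrl)
      data.frame(mouse = paste0("m", m), session = s, condition = cond,
                 correct = runif(n_trials) < p)
    }))
  }))
}

test_that("nested bootstrap recovers the observed effect without bias", {
  set.seed(2)
  dat <- nested_null_data(n_mice = 4, n_trials = 200, p_ctrl = 0.85,
                          p_stim = 0.65)
  res <- nested_bootstrap_effect(dat, n_resamples = 600)
  expect_s3_class(res, "bootstrap_result")
  expect_lt(res$observed_effect, 0)
  # resample distribution centers on the observed effect
  expect_lt(abs(res$summary[["mean"]] - res$observed_effect),
            3 * res$summary[["sd"]] / sqrt(600) * 5 + 1.5)
  expect_lt(res$p_one_tailed, 0.05)
})

test_that("nested bootstrap handles degenerate structure and missing arms", {
  set.seed(3)
  # single mouse, single session: reduces to a plain trial bootstrap
  dat <- nested_null_data(n_mice = 1, n_sessions = 1, n_trials = 400)
  res <- nested_bootstrap_effect(dat, n_resamples = 400)
  expect_true(is.finite(res$observed_effect))
  expect_gte(res$p_one_tailed, 0)
  # a mouse lacking the stim condition is dropped with a warning
  extra <- data.frame(mouse = "m9", session = 1, condition = "control",
                      correct = rep(TRUE, 50))
  expect_warning(nested_bootstrap_effect(rbind(dat, extra),
                                         n_resamples = 50),
                 "lacking")
})

test_that("IFI partitioning by preceding outcome matches the generator", {
  set.seed(4)
  p <- agent_params(error_ifi_multiplier = 1.5, p_within_bout = 1)
  n <- 6000
  outcomes <- sample(c("correct", "error"), n, TRUE)
  start <- numeric(n); endt <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    start[i] <- t; endt[i] <- t + 30
    t <- endt[i] + sample_engagement(p, endt[i], outcomes[i])
  }
  fx <- data.frame(start_time = start, end_time = endt,
                   last_outcome = outcomes)
  res <- ifi_by_outcome(fx)
  ratio <- res$mean_ifi[res$outcome == "error"] /
    res$mean_ifi[res$outcome == "correct"]
  expect_lt(abs(ratio - 1.5), 0.12)
  # fixations without scored trials leave their IFI unclassified
  fx$last_outcome[10] <- NA
  res2 <- ifi_by_outcome(fx)
  expect_equal(sum(res2$n), n - 2L)  # last fixation has no following IFI
})

test_that("spike-width classification and relative rate are exact on fixtures", {
  sweeps <- data.frame(intensity = rep(c(0.5, 5), each = 4),
                       sweep = rep(1:4, 2),
                       baseline_count = c(5, 5, 5, 5, 4, 6, 5, 5),
                       stim_count = c(13, 13, 13, 13, 2, 4, 3, 3))
  u <- classify_unit_and_modulation(sweeps, spike_width_ms = 0.40)
  expect_identical(u$cell_class, "FS")
  # hand-computed: baseline 5/0.5 = 10 Hz; stim 13/1.3 = 10 Hz -> ratio 1
  m1 <- u$modulation[u$modulation$intensity == 0.5, ]
  expect_equal(m1$baseline_rate, 10)
  expect_equal(m1$stim_rate, 10)
  expect_equal(m1$relative_rate, 1)
  # baseline 10 Hz, stim 3/1.3 Hz -> ratio 0.2308
  m2 <- u$modulation[u$modulation$intensity == 5, ]
  expect_equal(m2$relative_rate, (3 / 1.3) / 10)
  # boundary: width exactly 0.55 ms is pyramidal (strict <)
  expect_identical(classify_unit_and_modulation(sweeps, 0.55)$cell_class,
                   "pyramidal")
  expect_identical(classify_unit_and_modulation(sweeps, 0.549)$cell_class,
                   "FS")
  # paired t-test matches a direct call
  rates_b <- sweeps$baseline_count[5:8] / 0.5
  rates_s <- sweeps$stim_count[5:8] / 1.3
  expect_equal(m2$p_value, t.test(rates_s, rates_b, paired = TRUE)$p.value)
})

test_that("relative firing rate is scale invariant and flags zero baselines", {
  sweeps <- data.frame(intensity = 1, sweep = 1:5,
                       baseline_count = c(3, 4, 5, 4, 4),
                       stim_count = c(1, 2, 1, 2, 1))
  u1 <- classify_unit_and_modulation(sweeps, 0.8)
  sweeps2 <- sweeps
  sweeps2$baseline_count <- sweeps$baseline_count * 3
  sweeps2$stim_count <- sweeps$stim_count * 3
  u2 <- classify_unit_and_modulation(sweeps2, 0.8)
  expect_equal(u1$modulation$relative_rate, u2$modulation$relative_rate)
  zero <- data.frame(intensity = 1, sweep = 1:3,
                     baseline_count = 0, stim_count = 2)
  uz <- classify_unit_and_modulation(zero, 0.8)
  expect_true(is.na(uz$modulation$relative_rate))
  expect_true(uz$baseline_undefined)
})

test_that("a monotone simulated dose-response is recovered monotone", {
  set.seed(5)
  intensities <- c(0.28, 0.68, 1.7, 2.83, 5.66, 8.21)
  true_rel <- c(0.8, 0.6, 0.4, 0.25, 0.12, 0.05)  # progressive silencing
  n_sweeps <- 60
  sweeps <- do.call(rbind, lapply(seq_along(intensities), function(k) {
    data.frame(intensity = intensities[k], sweep = 1:n_sweeps,
               baseline_count = rpois(n_sweeps, 10 * 0.5),
               stim_count = rpois(n_sweeps, 10 * true_rel[k] * 1.3))
  }))
  u <- classify_unit_and_modulation(sweeps, 0.7)
  rel <- u$modulation$relative_rate[order(u$modulation$intensity)]
  expect_true(all(diff(rel) < 0.08))   # monotone within MC error
  expect_lt(max(abs(rel - true_rel)), 0.12)
  expect_true(all(u$modulation$p_value < 0.01))
})
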