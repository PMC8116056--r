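simple_trials <- function(S, A, R) {
  data.frame(trial_type = ifelse(S == 1, "lick_left", "lick_right"),
             choice = ifelse(A == 1, "left", "right"),
             outcome = ifelse(R == 1, "correct", "error"))
}

test_that("design coding: WSLS, S_avg, lag structure, row emission", {
  set.seed(1)
  n <- 40
  S <- sample(c(1, -1), n, TRUE); A <- sample(c(1, -1), n, TRUE)
  R <- ifelse(A == S, 1, -1)
  d <- build_design(simple_trials(S, A, R))
  expect_equal(nrow(d), n - 20)
  expect_equal(attr(d, "trial_pos"), 21:n)
  # WSLS = A1 * R1, elementwise
  expect_equal(d$WSLS, d$A1 * d$R1)
  expect_equal(d$A1, A[20:(n - 1)])
  expect_equal(d$S3, S[18:(n - 3)])
  expect_equal(d$Savg[1], mean(S[1:20]))
  expect_true(all(abs(d$Savg) <= 1))
  # previous trial chose left and was rewarded: WSLS = +1
  i <- which(d$A1 == 1 & d$R1 == 1)
  expect_true(all(d$WSLS[i] == 1))
  # chose left, unrewarded: WSLS = -1
  j <- which(d$A1 == 1 & d$R1 == -1)
  expect_true(all(d$WSLS[j] == -1))
  # 20 lick-right-instructing predecessors force S_avg = -1
  d2 <- build_design(simple_trials(rep(-1, 21), rep(1, 21), rep(-1, 21)))
  expect_equal(d2$Savg, -1)
  # fewer than 21 trials: empty design
  expect_equal(nrow(build_design(simple_trials(S[1:20], A[1:20], R[1:20]))),
               0)
})

test_that("ignore trials are dropped and history carries over them", {
  S <- rep(c(1, -1), 15)
  tr <- simple_trials(S, S, rep(1, 30))
  tr$choice[25] <- "ignore"; tr$outcome[25] <- "ignore"
  d <- build_design(tr)
  expect_equal(nrow(d), 29 - 20)
  # the trial after the ignore sees the last scored choice as A1
  sc <- tr[tr$choice != "ignore", ]
  A <- ifelse(sc$choice == "left", 1, -1)
  expect_equal(d$A1, A[20:(nrow(sc) - 1)])
})

test_that("MLE matches a dense grid-search maximizer on small designs", {
  set.seed(2)
  for (rep in 1:3) {
    n <- 20
    S0 <- sample(c(1, -1), n, TRUE)
    A1 <- sample(c(1, -1), n, TRUE)
    y <- rbinom(n, 1, plogis(0.8 * S0 - 0.4 * A1))
    d <- data.frame(S0 = S0, A1 = A1, y = y)
    fit <- fit_logistic(d, regressors = c("S0", "A1"), ridge = 0)
    # oracle: exhaustive grid over (bias, bS0, bA1)
    grid <- seq(-3, 3, by = 0.01)
    ll <- function(b0, b1, b2) {
      eta <- b0 + b1 * S0 + b2 * A1
      sum(y * eta - log1p(exp(eta)))
    }
    co <- coef(fit)
    # profile each coordinate at the fitted values of the others
    for (k in 1:3) {
      lls <- switch(k,
                    vapply(grid, function(g) ll(g, co[2], co[3]), numeric(1)),
                    vapply(grid, function(g) ll(co[1], g, co[3]), numeric(1)),
                    vapply(grid, function(g) ll(co[1], co[2], g), numeric(1)))
      expect_lt(abs(grid[which.max(lls)] - co[k]), 0.01 + 1e-9)
    }
    # fitted likelihood beats every grid point of a coarse full 3-D grid
    coarse <- seq(-3, 3, by = 0.25)
    best_grid <- max(vapply(coarse, function(b0)
      max(vapply(coarse, function(b1)
        max(vapply(coarse, function(b2) ll(b0, b1, b2), numeric(1))),
        numeric(1))), numeric(1)))
    expect_gte(fit$loglik + 1e-8, best_grid)
  }
})

test_that("null data give near-zero weights and chance cv accuracy", {
  set.seed(3)
  n <- 2000
  tr <- generate_policy_trials(n, w_stim = 0, w_hist = 0)
  tr$choice <- sample(tr$choice)  # break any residual structure
  d <- build_design(tr)
  fit <- fit_logistic(d)
  co <- coef(fit)[-1]
  # +/-1-coded regressors: tight null band; Savg has ~1/sqrt(20) the scale,
  # so its weight is bounded on the prediction (weight * regressor sd) scale
  expect_true(all(abs(co[setdiff(names(co), "Savg")]) < 0.15))
  expect_lt(abs(co[["Savg"]] * sd(d$Savg)), 0.15)
  cv <- crossval_predict(d)
  expect_lt(abs(cv$accuracy - 0.5), 0.06)
})

test_that("separable data are predicted perfectly and flagged cases warn", {
  S <- rep(c(1, -1), 30)
  tr <- simple_trials(S, S, rep(1, 60))
  d <- build_design(tr)
  fit <- fit_logistic(d, regressors = c("S0"))
  expect_true(all(predict(fit, d, type = "class") == d$y))
  # all-one-class response: bias-saturated fit with a warning
  tr2 <- simple_trials(S, rep(1, 60), ifelse(S == 1, 1, -1))
  d2 <- build_design(tr2)
  expect_warning(f2 <- fit_logistic(d2), "one class")
  expect_true(f2$degenerate)
  expect_true(all(predict(f2, d2, type = "class") == 1))
})

test_that("cross-validation guard zones are airtight in every window", {
  for (n_pos in c(500, 480, 520)) {
    blocks <- cv_blocks(n_pos)
    expect_equal(length(blocks), 9L)
    for (bl in blocks) {
      expect_equal(length(bl$test), 60L)
      expect_lte(length(bl$train), 400L)
      # exhaustive: no training trial within 20 trials of any test trial
      dmin <- min(vapply(bl$train, function(tr)
        min(abs(tr - bl$test)), numeric(1)))
      expect_gt(dmin, 20L)
      # training rows retain their own 20-trial history inside the window
      expect_true(all(bl$train >= 21L))
    }
  }
  expect_error(cv_blocks(70))
})

test_that("cv accuracy tracks the generative policy's closed form", {
  set.seed(4)
  tr <- generate_policy_trials(520, w_stim = 3, w_hist = 0)
  d <- build_design(tr)
  cv <- crossval_predict(d)
  expect_lt(abs(cv$accuracy - plogis(3)), 0.03)
})

test_that("partial-model bootstrap: degenerate, null and strong regressors", {
  set.seed(5)
  tr <- generate_policy_trials(520, w_stim = 2, w_hist = 0)
  d <- build_design(tr)
  # a zero-variance regressor yields identical predictions: strict p = 0,
  # tie fraction 1 (the literal consequence of the strict definition)
  d$Zero <- 0
  pv <- partial_model_pvalue(d, "Zero", n_boot = 200,
                             regressors = c("S0", "A1", "Zero"))
  expect_equal(pv$p_strict, 0)
  expect_equal(pv$tie_fraction, 1)
  expect_equal(pv$p_mid, 0.5)
  # the true driver S0 is overwhelmingly significant
  pv_s <- partial_model_pvalue(d, "S0", n_boot = 500,
                               regressors = c("S0", "A1"))
  expect_lt(pv_s$p_mid, 0.05)
})

test_that("sliding windows: count arithmetic and warning on short input", {
  set.seed(6)
  tr <- generate_policy_trials(1000, w_stim = 1.5)
  fits <- sliding_window_analysis(tr, window = 500, step = 100)
  expect_equal(length(fits), 6L)  # floor((1000-500)/100)+1
  expect_equal(vapply(fits, `[[`, numeric(1), "start"),
               c(1, 101, 201, 301, 401, 501))
  tr500 <- generate_policy_trials(500, w_stim = 1.5)
  expect_equal(length(sliding_window_analysis(tr500)), 1L)
  expect_warning(out <- sliding_window_analysis(tr500[1:499, ]),
                 "fewer scored trials")
  expect_equal(length(out), 0L)
})

test_that("reliance requires five consecutive significant windows", {
  p <- c(rep(0.01, 5), rep(0.5, 3))
  expect_true(regressor_reliance(matrix(p, ncol = 1))[1])
  p_alt <- rep(c(0.01, 0.5), 4)
  expect_false(regressor_reliance(matrix(p_alt, ncol = 1))[1])
  p4 <- c(rep(0.01, 4), 0.5, rep(0.01, 4))
  expect_false(regressor_reliance(matrix(p4, ncol = 1))[1])
})

test_that("shuffle control permutes only the response", {
  set.seed(7)
  tr <- generate_policy_trials(200, w_stim = 2)
  d <- build_design(tr)
  ds <- shuffle_control(d)
  regs <- setdiff(names(d), "y")
  expect_identical(d[regs], ds[regs])
  expect_identical(sort(d$y), sort(ds$y))
  # identity permutation leaves the design unchanged
  expect_identical(shuffle_control(d, perm = seq_len(nrow(d))), d)
})

test_that("parameter recovery at n = 5000 and the reduced-model contract", {
  set.seed(8)
  true <- c(w_stim = 2, w_hist = 0.8, bias = 0.3)
  tr <- generate_policy_trials(5000, w_stim = true[1], w_hist = true[2],
                               bias = true[3])
  d <- build_design(tr)
  fit <- fit_logistic(d, regressors = c("S0", "A1"))
  est <- coef(fit)[c("S0", "A1", "bias")]
  expect_lt(sqrt(mean((est - true)^2)), 0.3)
  # full model does not beat the generative reduced model by > 2 points
  cv_red <- crossval_predict(build_design(tr[1:1500, ]),
                             regressors = c("S0", "A1"))
  cv_full <- crossval_predict(build_design(tr[1:1500, ]))
  expect_lt(cv_full$accuracy - cv_red$accuracy, 0.02)
})
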