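# Choice-strategy logistic regression: design construction, ridge-stabilised
# maximum-likelihood fitting, history-excluding cross-validation,
# partial-model bootstrap selection, sliding windows, reliance
# classification, and the shuffle control.
#
# Regressors (+/-1 coded): S0 current stimulus (+1 = lick-left-instructing),
# S1..S5 stimulus history, A1..A5 choice history (+1 = licked left),
# R1..R5 reward history (+1 = rewarded), Savg = mean of the last 20 stimuli,
# WSLS = A1*R1, and a constant bias.  P(left) = plogis(sum(beta * x));
# P(left) > 0.5 predicts a left lick.

FULL_REGRESSORS <- c("S0", paste0("S", 1:5), paste0("A", 1:5),
                     paste0("R", 1:5), "Savg", "WSLS")

#' Build the choice-model design matrix
#'
#' Ignore trials are dropped first; on the remaining scored sequence the
#' history regressors are the previous scored trials' stimuli, choices and
#' rewards (so after an ignore the carried values are those of the last
#' scored trial).  Rows are emitted only for trials with at least 20
#' predecessors, as required by the 20-trial stimulus average.
#'
#' @param trials Data frame with columns `trial_type` (`"lick_left"` /
#'   `"lick_right"`, the instructed direction), `choice` (`"left"`/
#'   `"right"`/`"ignore"`), and `outcome` (`"correct"`/`"error"`/
#'   `"ignore"`).
#' @return A data frame of class `choice_design` with columns `S0`,
#'   `S1`..`S5`, `A1`..`A5`, `R1`..`R5`, `Savg`, `WSLS` and the response
#'   `y` (1 = left), plus attribute `trial_pos` giving each row's position
#'   in the scored sequence.
#' @export
build_design <- function(trials) {
  sc <- trials[trials$choice != "ignore", , drop = FALSE]
  n <- nrow(sc)
  if (n < 21L) {
    d <- as.data.frame(matrix(numeric(0), ncol = length(FULL_REGRESSORS) + 1,
                              dimnames = list(NULL,
                                              c(FULL_REGRESSORS, "y"))))
    return(structure(d, class = c("choice_design", "data.frame"),
                     trial_pos = integer(0)))
  }
  S <- ifelse(sc$trial_type == "lick_left", 1, -1)
  A <- ifelse(sc$choice == "left", 1, -1)
  R <- ifelse(sc$outcome == "correct", 1, -1)
  rows <- 21:n
  lagm <- function(v, k) v[rows - k]
  d <- data.frame(S0 = S[rows])
  for (k in 1:5) d[[paste0("S", k)]] <- lagm(S, k)
  for (k in 1:5) d[[paste0("A", k)]] <- lagm(A, k)
  for (k in 1:5) d[[paste0("R", k)]] <- lagm(R, k)
  d$Savg <- vapply(rows, function(i) mean(S[(i - 20):(i - 1)]), numeric(1))
  d$WSLS <- d$A1 * d$R1
  d$y <- as.integer(A[rows] == 1)
  structure(d, class = c("choice_design", "data.frame"), trial_pos = rows)
}

design_matrix <- function(design, regressors = NULL) {
  regs <- if (is.null(regressors))
    setdiff(names(design), "y") else regressors
  X <- cbind(bias = 1, as.matrix(design[regs]))
  storage.mode(X) <- "double"
  X
}

#' Fit the choice model by penalised maximum likelihood
#'
#' Iteratively reweighted least squares on the logistic likelihood with a
#' small ridge penalty (`ridge`, default 1e-4) on the non-bias weights to
#' stabilise separable designs.  Deterministic given the design.
#'
#' @param design A [build_design()] result (or any data frame with a binary
#'   `y` column and numeric regressors).
#' @param regressors Character vector of regressor columns to use (default:
#'   all non-response columns).
#' @param ridge Ridge penalty on non-bias weights.
#' @param max_iter,tol IRLS iteration controls.
#' @return An object of class `choice_fit` with `coefficients` (named,
#'   including `bias`), `converged`, `loglik`, `n`, and `degenerate`
#'   (TRUE with a warning flag when the response is all one class).
#' @export
fit_logistic <- function(design, regressors = NULL, ridge = 1e-4,
                         max_iter = 100L, tol = 1e-10) {
  y <- design$y
  if (length(y) < 1L) stop("empty design")
  X <- design_matrix(design, regressors)
  p <- ncol(X)
  pen <- rep(ridge, p); pen[1] <- 0       # bias unpenalised
  degenerate <- length(unique(y)) < 2L
  beta <- numeric(p)
  if (degenerate) {
    # bias-saturated fit: all weight on the intercept
    eps <- 1 / (2 * length(y))
    beta[1] <- stats::qlogis(max(eps, min(1 - eps, mean(y))))
    warning("response is all one class; returning bias-saturated fit")
  } else {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      XtW <- t(X * w)
      H <- XtW %*% X + diag(pen, p)
      beta_new <- drop(solve(H, XtW %*% z))
      if (max(abs(beta_new - beta)) < tol) {
        beta <- beta_new
        converged <- TRUE
        break
      }
      beta <- beta_new
    }
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 regressors = colnames(X)[-1],
                 ridge = ridge,
                 converged = if (degenerate) NA else converged,
                 degenerate = degenerate,
                 loglik = ll, n = length(y)),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("choice_fit on", x$n, "trials, logLik", format(x$loglik), "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Predict choice probabilities or classes
#'
#' @param object A `choice_fit`.
#' @param newdata A design data frame.
#' @param type `"response"` for P(left), `"class"` for 1/0 left/right by
#'   the P(left) > 0.5 rule.
#' @param zero Optional character vector of regressors whose fitted weight
#'   is set to zero before predicting (the partial model).
#' @param ... Unused.
#' @export
predict.choice_fit <- function(object, newdata, type = c("response", "class"),
                               zero = NULL, ...) {
  type <- match.arg(type)
  beta <- object$coefficients
  if (!is.null(zero)) {
    stopifnot(all(zero %in% names(beta)))
    beta[zero] <- 0
  }
  X <- design_matrix(newdata, object$regressors)
  p <- stats::plogis(drop(X %*% beta))
  if (type == "response") p else as.integer(p > 0.5)
}

#' History-excluding cross-validation scheme
#'
#' Within a window of `window` trials (default 500), 9 test blocks of 60
#' consecutive scored trials are placed with starts evenly spaced over the
#' usable positions (block starts from trial 21 to `window - 59`; blocks may
#' overlap).  For each block the training set is every design row at least
#' `guard` (20) trials away from the block on both sides, capped by the
#' window, so no training trial's history overlaps a test trial.
#'
#' @param n_pos Number of scored trials in the window.
#' @param n_blocks,block_len,guard Scheme parameters.
#' @return List of blocks, each with `test` (trial positions) and `train`.
#' @export
cv_blocks <- function(n_pos, n_blocks = 9L, block_len = 60L, guard = 20L) {
  first <- guard + 1L
  last_start <- n_pos - block_len + 1L
  if (last_start < first)
    stop("window too short for the cross-validation scheme")
  starts <- unique(round(seq(first, last_start, length.out = n_blocks)))
  max_train <- 400L
  lapply(starts, function(s) {
    test <- s:(s + block_len - 1L)
    excl <- max(first, s - guard):min(n_pos, s + block_len - 1L + guard)
    train <- setdiff(first:n_pos, excl)
    if (length(train) > max_train) {
      # cap at 400 training trials, keeping those closest to the test block
      d <- vapply(train, function(tr) min(abs(tr - test)), numeric(1))
      train <- sort(train[order(d)][seq_len(max_train)])
    }
    list(test = test, train = train)
  })
}

#' Cross-validated choice prediction
#'
#' Fits the model on each block's training rows and scores prediction
#' accuracy on the held-out block, averaging over blocks.
#'
#' @param design A [build_design()] result for one window.
#' @param regressors Regressor subset (default all).
#' @param n_blocks,block_len,guard See [cv_blocks()].
#' @param ridge Passed to [fit_logistic()].
#' @param keep_trials Logical; also return per-test-trial correctness for
#'   the full and per-regressor partial models (used by the bootstrap).
#' @return List with `accuracy` (mean over blocks), `block_accuracy`, and
#'   when `keep_trials` is TRUE, `full_correct` (0/1 vector pooled over
#'   blocks) and `partial_correct` (matrix, one column per regressor).
#' @export
crossval_predict <- function(design, regressors = NULL, n_blocks = 9L,
                             block_len = 60L, guard = 20L, ridge = 1e-4,
                             keep_trials = FALSE) {
  pos <- attr(design, "trial_pos")
  if (is.null(pos) || length(pos) == 0L) stop("empty design")
  n_pos <- max(pos)
  blocks <- cv_blocks(n_pos, n_blocks, block_len, guard)
  regs <- if (is.null(regressors)) setdiff(names(design), "y") else regressors
  acc <- numeric(length(blocks))
  fc <- list(); pc <- list()
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    tr <- design[pos %in% bl$train, , drop = FALSE]
    te <- design[pos %in% bl$test, , drop = FALSE]
    fit <- fit_logistic(tr, regressors = regs, ridge = ridge)
    pred <- predict(fit, te, type = "class")
    correct <- as.integer(pred == te$y)
    acc[b] <- mean(correct)
    if (keep_trials) {
      fc[[b]] <- correct
      pc[[b]] <- vapply(regs, function(r) {
        as.integer(predict(fit, te, type = "class", zero = r) == te$y)
      }, integer(nrow(te)))
    }
  }
  out <- list(accuracy = mean(acc), block_accuracy = acc,
              blocks = blocks)
  if (keep_trials) {
    out$full_correct <- unlist(fc)
    out$partial_correct <- do.call(rbind, pc)
  }
  out
}

#' Partial-model bootstrap p-value for one regressor
#'
#' The partial model zeroes the fitted weight of the regressor (no refit).
#' Test-set trials (pooled over the cross-validation blocks) are resampled
#' with replacement `n_boot` times; the strict p-value is the fraction of
#' resamples in which the partial model predicts strictly better than the
#' full model, and the mid-p variant counts exact ties as one half.
#'
#' @param design A window's [build_design()] result.
#' @param regressor Regressor name (e.g. `"S0"`, `"A1"`, `"WSLS"`).
#' @param n_boot Number of bootstrap resamples.
#' @param regressors Model regressor set (default all).
#' @param cv Optionally, a precomputed [crossval_predict()] result with
#'   `keep_trials = TRUE`.
#' @param ... Passed to [crossval_predict()].
#' @return List with `p_strict`, `p_mid`, `tie_fraction`, `n_test`.
#' @export
partial_model_pvalue <- function(design, regressor, n_boot = 1000L,
                                 regressors = NULL, cv = NULL, ...) {
  if (is.null(cv))
    cv <- crossval_predict(design, regressors = regressors,
                           keep_trials = TRUE, ...)
  d <- cv$partial_correct[, regressor] - cv$full_correct
  n <- length(d)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  s <- colSums(matrix(d[idx], nrow = n))
  list(p_strict = mean(s > 0),
       p_mid = mean(s > 0) + 0.5 * mean(s == 0),
       tie_fraction = mean(s == 0),
       n_test = n)
}

#' Sliding-window strategy analysis
#'
#' Applies the choice model in windows of `window` scored trials advancing
#' by `step`, fitting, cross-validating, and (optionally) computing
#' partial-model bootstrap p-values per regressor in each window.
#'
#' @param trials Trial data frame (see [build_design()]).
#' @param window,step Window length and step in scored trials.
#' @param regressors Model regressor set (default the full set).
#' @param n_boot Bootstrap resamples per regressor p-value; 0 skips the
#'   p-values.
#' @param ridge Passed to [fit_logistic()].
#' @return A list of class `sliding_fits`: per window, `start` (scored-trial
#'   index), `fit`, `cv_accuracy`, and `pvalues` (mid-p per regressor,
#'   with strict p in attribute `"strict"`).  Empty (with a warning) when
#'   fewer than `window` scored trials exist.
#' @export
sliding_window_analysis <- function(trials, window = 500L, step = 100L,
                                    regressors = NULL, n_boot = 0L,
                                    ridge = 1e-4) {
  sc <- trials[trials$choice != "ignore", , drop = FALSE]
  N <- nrow(sc)
  if (N < window) {
    warning("fewer scored trials than one window; returning no fits")
    return(structure(list(), class = "sliding_fits"))
  }
  starts <- seq(1L, N - window + 1L, by = step)
  regs <- if (is.null(regressors)) FULL_REGRESSORS else regressors
  fits <- lapply(starts, function(s) {
    d <- build_design(sc[s:(s + window - 1L), , drop = FALSE])
    fit <- fit_logistic(d, regressors = regs, ridge = ridge)
    cv <- crossval_predict(d, regressors = regs, ridge = ridge,
                           keep_trials = n_boot > 0L)
    pv <- NULL
    if (n_boot > 0L) {
      pp <- lapply(regs, function(r)
        partial_model_pvalue(d, r, n_boot = n_boot, cv = cv))
      pv <- stats::setNames(vapply(pp, `[[`, numeric(1), "p_mid"), regs)
      attr(pv, "strict") <- stats::setNames(
        vapply(pp, `[[`, numeric(1), "p_strict"), regs)
    }
    list(start = s, fit = fit, cv_accuracy = cv$accuracy, pvalues = pv)
  })
  structure(fits, class = "sliding_fits", window = window, step = step)
}

#' Classify regressor reliance across windows
#'
#' A regressor is relied upon if its p-value is below `alpha` in at least
#' `k` consecutive windows (with the default 100-trial step, five windows
#' span 1000 trials).
#'
#' @param pmat Matrix of p-values, windows in rows, regressors in columns
#'   (or a `sliding_fits` object with p-values).
#' @param alpha Significance level.
#' @param k Required run length.
#' @return Named logical vector, one element per regressor.
#' @export
regressor_reliance <- function(pmat, alpha = 0.05, k = 5L) {
  if (inherits(pmat, "sliding_fits"))
    pmat <- do.call(rbind, lapply(pmat, `[[`, "pvalues"))
  if (is.null(dim(pmat))) pmat <- matrix(pmat, ncol = 1)
  apply(pmat < alpha, 2, function(sig) {
    r <- rle(sig)
    any(r$values & r$lengths >= k)
  })
}

#' Shuffle control
#'
#' Permutes the response vector of a design while leaving every regressor
#' column (built from the original stimulus, choice and reward history)
#' untouched.
#'
#' @param design A [build_design()] result.
#' @param perm Optional permutation (default: random).
#' @return The shuffled design.
#' @export
shuffle_control <- function(design, perm = NULL) {
  n <- nrow(design)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n)
  design$y <- design$y[perm]
  design
}
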