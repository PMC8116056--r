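mk_history <- function(outcomes, types = NULL) {
  n <- length(outcomes)
  if (is.null(types))
    types <- rep(c("lick_left", "lick_right"), length.out = n)
  data.frame(trial_type = types, outcome = outcomes)
}

test_that("stage advancement follows the 70/75/70 criteria on full blocks", {
  st <- task_state()
  st$scored_since_change <- 30L
  # 22/30 = 73% passes the 70% directional criterion
  h <- mk_history(c(rep("correct", 22), rep("error", 8)))
  st2 <- advance_stage(st, h)
  expect_identical(st2$stage, "discrimination")
  # 74% does not pass the 75% discrimination criterion
  st2$scored_since_change <- 100L
  h <- mk_history(c(rep("correct", 22), rep("error", 8)))  # 73%
  expect_identical(advance_stage(st2, h)$stage, "discrimination")
  # 23/30 = 77% does
  st2$scored_since_change <- 30L
  h <- mk_history(c(rep("correct", 23), rep("error", 7)))
  st3 <- advance_stage(st2, h)
  expect_identical(st3$stage, "delay")
  expect_equal(st3$delay_duration, 0.3)
  # criteria are not evaluated on partial or mid-block windows
  st$scored_since_change <- 29L
  h <- mk_history(rep("correct", 30))
  expect_identical(advance_stage(st, h)$stage, "directional")
  st$scored_since_change <- 31L
  expect_identical(advance_stage(st, h)$stage, "directional")
})

test_that("delay ramp 0.3 -> 1.3 s completes in exactly 5 criterion passes", {
  st <- task_state()
  st$stage <- "delay"; st$delay_duration <- 0.3
  h <- mk_history(rep("correct", 30))
  passes <- 0L
  while (st$stage == "delay") {
    st$scored_since_change <- 30L
    st <- advance_stage(st, h)
    passes <- passes + 1L
    expect_lt(passes, 10L)
  }
  expect_equal(passes, 5L)
  expect_identical(st$stage, "complete")
  expect_equal(st$delay_duration, 1.3)
})

test_that("directional block rule switches type after three correct", {
  st <- task_state()
  expect_identical(select_trial_type(st)$trial_type, "lick_left")
  st <- record_trial_result(st, "lick_left", "correct")
  st <- record_trial_result(st, "lick_left", "error")
  st <- record_trial_result(st, "lick_left", "correct")
  expect_identical(select_trial_type(st)$trial_type, "lick_left")
  st <- record_trial_result(st, "lick_left", "correct")   # 3rd correct
  expect_identical(select_trial_type(st)$trial_type, "lick_right")
})

test_that("forced repeat engages after 3 consecutive errors, clears after 2 correct", {
  st <- task_state(); st$stage <- "discrimination"
  h <- mk_history(rep("error", 3), types = rep("lick_right", 3))
  aa <- evaluate_autoassist(st, h)
  expect_true("forced_repeat" %in% aa$actions)
  st <- aa$state
  expect_identical(st$forced_repeat_type, "lick_right")
  expect_identical(select_trial_type(st)$trial_type, "lick_right")
  st <- record_trial_result(st, "lick_right", "correct")
  expect_identical(select_trial_type(st)$trial_type, "lick_right")
  st <- record_trial_result(st, "lick_right", "correct")
  expect_identical(st$forced_repeat_type, NA_character_)
})

test_that("free reward follows five consecutive errors in one type", {
  st <- task_state(); st$stage <- "discrimination"
  h <- mk_history(c(rbind(rep("correct", 5), rep("error", 5))),
                  types = c(rbind(rep("lick_left", 5), rep("lick_right", 5))))
  aa <- evaluate_autoassist(st, h)
  expect_true("free_reward" %in% aa$actions)
  expect_identical(aa$free_reward_type, "lick_right")
  # four consecutive errors are not enough
  h4 <- mk_history(c("correct", rep("error", 4)),
                   types = c("lick_right", rep("lick_right", 4)))
  aa4 <- evaluate_autoassist(task_state(), h4)
  expect_false("free_reward" %in% aa4$actions)
})

test_that("bias detection moves the lickport toward the worse side", {
  st <- task_state(); st$stage <- "discrimination"
  # 50 scored trials: left 90% on 25, right 55% (approx) on 25
  types <- rep(c("lick_left", "lick_right"), 25)
  out_l <- c(rep("correct", 23), rep("error", 2))
  out_r <- c(rep("correct", 13), rep("error", 12))
  h <- mk_history(c(rbind(out_l, out_r)), types = types)
  aa <- evaluate_autoassist(st, h)
  expect_true("move_lickport" %in% aa$actions)
  expect_true(aa$state$lickport_offset > 0)  # right spout moved closer
  # balanced performance: no bias action
  h <- mk_history(rep(c("correct", "correct", "correct", "correct", "error"),
                      20),
                  types = rep(c("lick_left", "lick_right"), 50))
  aa <- evaluate_autoassist(task_state(), h)
  expect_false("move_lickport" %in% aa$actions)
})

test_that("reweighting presents the worse trial type more often, capped", {
  st <- task_state(); st$stage <- "discrimination"
  types <- rep(c("lick_left", "lick_right"), 15)
  out <- ifelse(types == "lick_left", "correct",
                rep(c("error", "error", "correct", "correct"),
                    length.out = 30))
  h <- mk_history(out, types = types)
  aa <- evaluate_autoassist(st, h)
  probs <- aa$state$trial_type_probabilities
  expect_gt(probs[["lick_right"]], 0.5)
  expect_lte(probs[["lick_right"]], 0.8)
  expect_equal(sum(probs), 1)
})

test_that("contingency reversal flips on >80% over 100 scored trials, strictly", {
  st <- task_state(reversal_mode = TRUE); st$stage <- "discrimination"
  st$scored_since_change <- 100L
  h85 <- mk_history(c(rep("correct", 85), rep("error", 15)))
  st2 <- check_contingency_reversal(st, h85)
  expect_identical(st2$contingency, "reversed")
  expect_equal(st2$n_reversals, 1L)
  expect_equal(st2$scored_since_change, 0L)
  # exactly 80/100 does not flip
  h80 <- mk_history(c(rep("correct", 80), rep("error", 20)))
  expect_identical(check_contingency_reversal(st, h80)$contingency,
                   "standard")
  # two flips return to the standard mapping (involution)
  st2$scored_since_change <- 100L
  st3 <- check_contingency_reversal(st2, h85)
  expect_identical(st3$contingency, "standard")
  for (tt in c("lick_left", "lick_right"))
    expect_identical(pole_position(tt, "standard"),
                     pole_position(tt, "standard"))
})

test_that("photostim assignment hits ~10% of trials with the right epochs", {
  set.seed(123)
  n <- 1e4
  hits <- 0L
  for (i in seq_len(n))
    if (!is.null(assign_photostim(c("sample", "delay", "response"),
                                  c(0.3, 1.5, 3.5))))
      hits <- hits + 1L
  # binomial 99% CI around 0.10 at n = 1e4
  ci <- qbinom(c(0.005, 0.995), n, 0.10) / n
  expect_gte(hits / n, ci[1])
  expect_lte(hits / n, ci[2])
  # restricted epochs are honored
  set.seed(5)
  eps <- replicate(200, {
    a <- assign_photostim("delay", 1.5, p = 1)
    a$epoch
  })
  expect_true(all(eps == "delay"))
  # p = 0 never assigns; empty intensity set is a configuration error
  expect_null(assign_photostim(p = 0))
  expect_error(assign_photostim(intensity_set = numeric(0)))
})

test_that("trial-type draws are balanced under equal probabilities", {
  set.seed(99)
  st <- task_state(); st$stage <- "discrimination"
  draws <- replicate(1e4, select_trial_type(st)$trial_type)
  frac <- mean(draws == "lick_left")
  ci <- qbinom(c(0.005, 0.995), 1e4, 0.5) / 1e4
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})

test_that("forced repeat cannot deadlock for an agent with any accuracy", {
  set.seed(21)
  # accuracy 0.3: expected exit time from a 2-correct requirement is finite
  for (rep in 1:20) {
    st <- task_state(); st$stage <- "discrimination"
    st$forced_repeat_type <- "lick_left"
    n <- 0L
    while (!is.na(st$forced_repeat_type) && n < 1000L) {
      out <- if (runif(1) < 0.3) "correct" else "error"
      st <- record_trial_result(st, "lick_left", out)
      n <- n + 1L
    }
    expect_true(is.na(st$forced_repeat_type))
  }
})
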