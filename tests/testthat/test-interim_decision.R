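# Effect estimation and the pre-specified interim/final decision rule.

test_that("cohens_d matches hand computation and is antisymmetric", {
  r <- cohens_d(c(3, 4, 5), c(1, 2, 3))
  expect_equal(r$d, 2)
  expect_equal(r$pooled_sd, 1)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  # identical non-constant groups: defined, and exactly zero
  expect_equal(cohens_d(a, a)$d, 0)
})

test_that("degenerate samples give the undefined-effect error", {
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled standard deviation")
  expect_error(cohens_d(3, c(1, 2)), "at least 2")
})

test_that("interim_decide implements the three-way rule", {
  plan <- default_plan
  p <- default_params
  set.seed(11)
  ctrl <- rnorm(15, 42, 2.5)
  # null effect: predicted power ~ alpha-level, stop for futility
  r0 <- interim_decide(ctrl + 0.01 * rnorm(15), ctrl, plan, stage = 1)
  expect_identical(r0$decision, "stop_futility")
  expect_lt(r0$predicted_power, 0.80)
  # huge effect: p-value far below the interim level, stop for efficacy
  r2 <- interim_decide(ctrl + 10, ctrl, plan, stage = 1)
  expect_identical(r2$decision, "stop_efficacy")
  expect_lt(r2$p_value, 1e-6)
  # moderate effect: |d| = 1.0 clears futility (cutoff 0.57) but its
  # p-value (~t = 1.0 * sqrt(15/2) = 2.74, p ~ 0.011) exceeds 0.0013
  x <- scale(rnorm(15))[, 1] * 2.5 + 42   # exactly mean 42, sd 2.5
  y <- scale(rnorm(15))[, 1] * 2.5 + 44.5 # shifted by d = 1.0
  r1 <- interim_decide(y, x, plan, stage = 1)
  expect_equal(r1$observed_d, 1.0, tolerance = 1e-9)
  p_manual <- 2 * pt(1.0 * sqrt(15 / 2), 28, lower.tail = FALSE)
  expect_equal(r1$p_value, p_manual, tolerance = 1e-9)
  expect_identical(r1$decision, "continue")
})

test_that("the predicted-power rule coincides with the futility-d cutoff", {
  plan <- default_plan
  set.seed(21)
  mismatches <- 0L
  for (i in 1:2000) {
    d_true <- runif(1, -1.5, 1.5)
    r <- interim_decide(rnorm(15, d_true), rnorm(15), plan, stage = 1)
    by_cutoff <- abs(r$observed_d) < plan$futility_d[1]
    if ((r$decision == "stop_futility") != by_cutoff) {
      # only tolerated within root-finder distance of the boundary
      expect_lt(abs(abs(r$observed_d) - plan$futility_d[1]), 1e-6)
      mismatches <- mismatches + 1L
    }
  }
  expect_lt(mismatches, 2L)
})

test_that("under the null, stage-1 efficacy stops occur at the interim level", {
  plan <- default_plan
  reps <- 4e4
  set.seed(31)
  x <- matrix(rnorm(reps * 15), reps); y <- matrix(rnorm(reps * 15), reps)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  sp2 <- (apply(x, 1, var) + apply(y, 1, var)) / 2
  p <- 2 * pt(abs((m1 - m2) / sqrt(sp2 * 2 / 15)), 28, lower.tail = FALSE)
  # efficacy requires passing futility first, which a p <= 0.0013 result
  # always does at n = 15, so the stop rate is the nominal level
  rate <- mean(p <= plan$efficacy_alpha[1])
  expect_lt(abs(rate - 0.0013), mc_3se(0.0013, reps))
})

test_that("stage/plan mismatches and short samples are configuration errors", {
  plan <- default_plan
  expect_error(interim_decide(rnorm(15), rnorm(15), plan), "stage = k")
  expect_error(interim_decide(rnorm(15), rnorm(15), plan, stage = 9),
               "no stage 9")
  expect_error(interim_decide(rnorm(5), rnorm(15), plan, stage = 1),
               "interim_n")
  expect_warning(interim_decide(rnorm(20, 5), rnorm(20), plan, stage = 1),
                 "exceed")
})

test_that("summary-statistic entry point agrees with participant-level data", {
  plan <- default_plan
  set.seed(41)
  x <- rnorm(15, 45, 2.5); y <- rnorm(15, 42, 2.5)
  a <- interim_decide(x, y, plan, stage = 1)
  b <- interim_decide_stats(15, mean(x), sd(x), 15, mean(y), sd(y),
                            plan, stage = 1)
  expect_equal(a$observed_d, b$observed_d)
  expect_equal(a$p_value, b$p_value)
  expect_identical(a$decision, b$decision)
})

test_that("final_analyze applies the final (or spending-adjusted) level", {
  p <- default_params
  set.seed(51)
  x <- rnorm(50, 42, 2.5)
  same <- final_analyze(x + rnorm(50, 0, 1e-8), x, p)
  expect_gt(same$p_value, 0.9)
  expect_false(same$significant)
  # textbook check: p-value equals the closed-form t CDF expression
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 9)
  res <- final_analyze(a, b, p)
  sp <- sqrt((4 * var(a) + 4 * var(b)) / 8)
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(2 / 5))
  expect_equal(res$p_value, 2 * pt(abs(tstat), 8, lower.tail = FALSE))
  # degenerate level: alpha_final = 1 - eps declares everything significant
  p1 <- design_params(alpha_final = 1 - 1e-12)
  expect_true(final_analyze(rnorm(50), rnorm(50), p1)$significant)
  # strict spending reduces the final level by the interim spend
  ps <- design_params(strict_spending = TRUE)
  plan <- plan_design(ps)
  r <- final_analyze(rnorm(50, 1), rnorm(50), ps, plan, stage = 1)
  expect_equal(r$alpha_used, 0.05 - 0.0013)
})

test_that("the CSV interface carries only labels and endpoints", {
  plan <- default_plan
  f <- tempfile(fileext = ".csv")
  set.seed(61)
  df <- data.frame(participant_id = sprintf("P%02d", 1:30),
                   group = rep(c("test", "control"), each = 15),
                   endpoint = c(rnorm(15, 46, 2.5), rnorm(15, 42, 2.5)))
  write.csv(df, f, row.names = FALSE)
  g <- read_group_samples(f)
  expect_length(g$test, 15)
  r <- interim_decide(g$test, g$control, plan, stage = 1)
  expect_true(r$decision %in% c("continue", "stop_futility", "stop_efficacy"))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1, arm = "a", value = 1), bad, row.names = FALSE)
  expect_error(read_group_samples(bad), "columns")
  unlink(c(f, bad))
})
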