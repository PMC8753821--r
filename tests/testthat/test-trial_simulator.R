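# Monte-Carlo operating characteristics of the interim rule.

test_that("a fixed seed makes the simulation fully reproducible", {
  a <- simulate_fixed_effect(0.6, default_params, reps = 500, seed = 7)
  b <- simulate_fixed_effect(0.6, default_params, reps = 500, seed = 7)
  expect_identical(a, b)
})

test_that("efficacy stops at d = 1.6 match the analytic interim power", {
  reps <- 1e4
  s <- simulate_fixed_effect(1.6, default_params, reps = reps, seed = 12)
  target <- power_t2(1.6, 15, default_plan$efficacy_alpha[1])
  expect_lt(abs(s$rates[["stop_efficacy"]] - target), mc_3se(target, reps))
})

test_that("null halts match the exact central-t oracle for |d-hat| < cutoff", {
  # under d = 0 the interim statistic t = d-hat * sqrt(n/2) is central
  # t(2n-2), so P(halt) = P(|t| < futility_d * sqrt(n/2)) exactly
  reps <- 1e4
  s <- simulate_fixed_effect(0, default_params, reps = reps, seed = 13)
  cutoff <- default_plan$futility_d[1] * sqrt(15 / 2)
  target <- pt(cutoff, 28) - pt(-cutoff, 28)
  expect_lt(abs(s$rates[["halt"]] - target), mc_3se(target, reps))
})

test_that("decision rates partition and stay in [0, 1]", {
  for (d in c(0, 0.6, 1.6)) {
    s <- simulate_fixed_effect(d, default_params, reps = 2000,
                               seed = 100 + 10 * d)
    expect_equal(sum(s$rates), 1)
    expect_true(all(s$rates >= 0 & s$rates <= 1))
    expect_true(s$correct_ci[1] <= s$correct_decision &&
                s$correct_decision <= s$correct_ci[2])
  }
})

test_that("decisions are equivariant to the endpoint scale", {
  a <- simulate_fixed_effect(0.6, default_params, reps = 1000, seed = 5,
                             sd = 1)
  b <- simulate_fixed_effect(0.6, default_params, reps = 1000, seed = 5,
                             sd = 2.5)
  expect_equal(a$rates, b$rates)
  expect_equal(a$correct_decision, b$correct_decision)
})

test_that("disabling the efficacy rule folds efficacy stops into continues", {
  s <- simulate_fixed_effect(1.6, default_params, reps = 2000, seed = 6,
                             efficacy_rule = FALSE)
  expect_identical(s$rates[["stop_efficacy"]], 0)
  # continue rate equals the analytic pass-futility probability: the
  # noncentral-t oracle for P(|d-hat| >= cutoff)
  cutoff <- default_plan$futility_d[1] * sqrt(15 / 2)
  ncp <- 1.6 * sqrt(15 / 2)
  target <- 1 - (pt(cutoff, 28, ncp) - pt(-cutoff, 28, ncp))
  expect_lt(abs(s$rates[["continue"]] - target), mc_3se(target, 2000))
})

test_that("bootstrap CIs cover the long-run correct rate most of the time", {
  cutoff <- default_plan$futility_d[1] * sqrt(15 / 2)
  # long-run correct-decision rate at d = 0: correct = halt & final
  # non-significant, or pass & final significant; estimate it once with a
  # large run and check smaller runs' CIs cover it
  big <- simulate_fixed_effect(0, default_params, reps = 2e4, seed = 77)
  truth <- big$correct_decision
  hits <- 0L
  for (i in 1:20) {
    s <- simulate_fixed_effect(0, default_params, reps = 2000, seed = 200 + i)
    if (s$correct_ci[1] <= truth && truth <= s$correct_ci[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 15L)  # smoke-level coverage for a 95% interval
})

test_that("the interim-timing sweep shows diminishing returns", {
  tab <- interim_timing_sweep(c(5, 10, 15, 25, 50), true_ds = c(0, 0.6),
                              reps = 4000, seed = 3)
  expect_identical(nrow(tab), 10L)
  # more interim information cannot hurt on average (null case), up to MC
  # noise
  null_pct <- tab$correct_pct[tab$true_d == 0]
  expect_true(all(diff(null_pct) > -2.5))
  expect_gt(null_pct[5], null_pct[1])
  # interim = final: the null correct rate peaks but stays below 100%
  # because the futility bar (predicted power >= 80%, i.e. |d-hat| >= 0.57
  # at n = 50) is stricter than bare final significance (|d-hat| >= 0.40),
  # so a sliver of would-be-significant trials is still halted; the
  # residual equals P(0.40 <= |d-hat| < 0.57) under the null
  expect_equal(max(null_pct), null_pct[5])
  t_cut <- c(qt(0.975, 98), minimum_detectable_d(50, 0.8, 0.05) * sqrt(25))
  residual <- (pt(t_cut[2], 98) - pt(t_cut[1], 98)) * 2
  expect_equal(null_pct[5] / 100, 1 - residual,
               tolerance = 3 * sqrt(residual / 4000) / (1 - residual))
  # marginal gain per added participant shrinks between early and late grid
  d6 <- tab[tab$true_d == 0.6, ]
  expect_gt(d6$marginal_gain_pct[2], d6$marginal_gain_pct[5])
  expect_true(is.na(d6$marginal_gain_pct[1]))
})

test_that("adaptive pathways respect the budget and per-group analytics", {
  reps <- 400
  res <- simulate_adaptive_study(default_params, c(0, 0, 0), reps = reps,
                                 seed = 9)
  expect_lte(res$max_consumed, 100)
  # each null group stops (futility, rarely efficacy) with probability
  # ~ the central-t oracle, so most studies walk through all three groups
  cutoff <- default_plan$futility_d * sqrt(15 / 2)
  p_halt <- pt(cutoff, 28) - pt(-cutoff, 28)
  reach3 <- sum(res$pathways[grepl(">.*>", names(res$pathways))])
  expect_gt(reach3, 0.6)
  expect_lt(abs(reach3 - prod(p_halt[1:2])), 3 * sqrt(0.25 / reps) + 0.02)
  # a huge group-1 effect stops for efficacy at the analytic power
  res2 <- simulate_adaptive_study(default_params, c(3, 0, 0), reps = reps,
                                  seed = 10)
  eff1 <- res2$group_decisions["stop_efficacy", "group1"]
  target <- power_t2(3, 15, default_plan$efficacy_alpha[1])
  expect_lt(abs(eff1 - target), mc_3se(target, reps) + 0.01)
})
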