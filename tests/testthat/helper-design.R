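# Shared fixtures: the default design and its schedule, plus a brute-force
# Monte-Carlo two-sample t-test oracle used to cross-check the analytic
# power function. The oracle simulates actual t-tests and never calls the
# package's power code.

default_params <- design_params()
default_plan <- plan_design(default_params)

# MC estimate of two-sided pooled t-test rejection probability
mc_power_oracle <- function(d, n, alpha, reps = 2e5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(reps * n, d, 1), reps, n)
  y <- matrix(rnorm(reps * n, 0, 1), reps, n)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  sp2 <- ((n - 1) * v1 + (n - 1) * v2) / (2 * n - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * 2 / n)
  p <- 2 * pt(abs(tstat), 2 * n - 2, lower.tail = FALSE)
  mean(p <= alpha)
}

# 3 Monte-Carlo standard errors for a proportion
mc_3se <- function(p, reps) 3 * sqrt(p * (1 - p) / reps)
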