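# Exact power mathematics for the two-sample two-sided t-test.
# Every other module (planner, interim decision, simulator) builds on these
# three functions, so they use the noncentral-t distribution throughout
# rather than the large-sample normal approximation.

#' Exact power of a two-sided two-sample t-test
#'
#' Computes the probability of rejecting the null hypothesis of equal means
#' in a pooled-variance two-sample t-test with equal group sizes, using the
#' noncentral t distribution. With `n` participants per group the test has
#' `df = 2n - 2` degrees of freedom and noncentrality `d * sqrt(n / 2)`,
#' where `d` is the standardized mean difference (Cohen's d).
#'
#' @param d Cohen's d, the standardized mean difference
#'   `(mu_test - mu_control) / sigma`. May be signed; power is symmetric in
#'   the sign of `d`.
#' @param n_per_group Integer number of participants per group (>= 2).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return The rejection probability, a number in (0, 1). At `d = 0` this is
#'   exactly `alpha` (the size of the test).
#' @examples
#' power_t2(1.6, 15, 0.0013)   # ~0.776
#' power_t2(0, 30, 0.05)       # 0.05: size under the null
#' @seealso [required_n()], [minimum_detectable_d()]
#' @export
power_t2 <- function(d, n_per_group, alpha) {
  check_scalar(d, "d")
  check_n_per_group(n_per_group)
  check_alpha(alpha)
  df <- 2 * n_per_group - 2
  ncp <- abs(d) * sqrt(n_per_group / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  # two-sided rejection region |T| > tcrit under T ~ t(df, ncp)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Smallest per-group sample size achieving a target power
#'
#' Inverts [power_t2()]: returns the smallest integer `n` per group such
#' that the exact noncentral-t power at effect size `d` reaches `power`.
#' The search is seeded from the normal-approximation sample size
#' `2 * ((z_{1-alpha/2} + z_{power}) / d)^2` and then walks to the exact
#' boundary, so it is fast even for tiny effects.
#'
#' @inheritParams power_t2
#' @param power Target power, in (0, 1).
#' @return Integer sample size per group (total sample is twice this).
#' @examples
#' required_n(0.6, 0.80, 0.05)  # 45 per group, 90 in total
#' @export
required_n <- function(d, power, alpha) {
  check_scalar(d, "d")
  check_alpha(alpha)
  check_power(power)
  if (d == 0) {
    stop("required_n(): power ", power, " is unachievable at d = 0; ",
         "no finite sample size rejects H0 with probability above alpha.",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- max(2L, as.integer(ceiling(2 * (z / d)^2)) - 2L)
  while (power_t2(d, n, alpha) < power) n <- n + 1L
  # the seed may overshoot: walk down to the smallest qualifying n
  while (n > 2L && power_t2(d, n - 1L, alpha) >= power) n <- n - 1L
  n
}

#' Minimum detectable standardized effect size
#'
#' The (positive) Cohen's d at which a two-sided two-sample t-test with
#' `n_per_group` participants per group attains exactly the target power at
#' level `alpha`. Found by root-finding on the exact noncentral-t power
#' function; this is the "futility effect size" of a sequential design
#' stage when evaluated at that stage's final sample size.
#'
#' @inheritParams power_t2
#' @inheritParams required_n
#' @param d_max Upper bound for the root search (default 20; no realistic
#'   design needs a larger standardized effect).
#' @return Positive Cohen's d solving `power_t2(d, n, alpha) == power`.
#' @examples
#' minimum_detectable_d(50, 0.80, 0.05)  # ~0.57
#' minimum_detectable_d(25, 0.80, 0.05)  # ~0.81
#' @export
minimum_detectable_d <- function(n_per_group, power, alpha, d_max = 20) {
  check_n_per_group(n_per_group)
  check_alpha(alpha)
  check_power(power)
  f <- function(d) power_t2(d, n_per_group, alpha) - power
  if (f(d_max) < 0) {
    stop("minimum_detectable_d(): no effect size in (0, ", d_max,
         "] reaches power ", power, " with n = ", n_per_group,
         " per group at alpha = ", alpha, ".", call. = FALSE)
  }
  stats::uniroot(f, lower = 1e-10, upper = d_max, tol = 1e-10)$root
}

# ---- shared argument checks ------------------------------------------------

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number.", call. = FALSE)
  invisible(x)
}

check_n_per_group <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < 2 || n != round(n))
    stop("n_per_group must be a single integer >= 2 (df = 2n - 2 must be ",
         "positive).", call. = FALSE)
  invisible(n)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1.", call. = FALSE)
  invisible(alpha)
}

check_power <- function(power) {
  if (!is.numeric(power) || length(power) != 1L || !is.finite(power) ||
      power <= 0 || power >= 1)
    stop("power must lie strictly between 0 and 1.", call. = FALSE)
  invisible(power)
}
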