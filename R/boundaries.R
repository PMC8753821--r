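# Alpha-spending and two-look group-sequential boundaries.
#
# Interim looks are indexed by the information fraction t = n_interim / n_final
# (sample-size information under equal variance). Under the null, the interim
# and final z statistics are jointly normal with corr(Z_j, Z_k) = sqrt(t_j/t_k)
# for j <= k; crossing probabilities are computed exactly by the standard
# continuation-density recursion on the Brownian (score) scale.

#' Lan-DeMets O'Brien-Fleming cumulative alpha spending
#'
#' The two-sided O'Brien-Fleming-type spending function
#' `alpha(t) = 2 * (1 - Phi(z_{alpha/2} / sqrt(t)))`: very little alpha is
#' spent at early information fractions, and the full `alpha_total` is
#' exhausted at `t = 1`.
#'
#' @param t Information fraction(s) in (0, 1]. Vectorized.
#' @param alpha_total Overall two-sided significance level (default 0.05).
#' @return Cumulative two-sided alpha spent by information fraction `t`.
#' @examples
#' of_spending_cumulative(1, 0.05)      # 0.05
#' of_spending_cumulative(0.3, 0.05)    # ~3.5e-4
#' @export
of_spending_cumulative <- function(t, alpha_total = 0.05) {
  check_alpha(alpha_total)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0) || any(t > 1))
    stop("information fraction t must lie in (0, 1].", call. = FALSE)
  2 * stats::pnorm(stats::qnorm(1 - alpha_total / 2) / sqrt(t),
                   lower.tail = FALSE)
}

#' Overall type-1 error of a two-sided group-sequential schedule
#'
#' Probability, under the null hypothesis, that at least one look of a
#' two-sided group-sequential design rejects, given per-look nominal
#' two-sided levels and information fractions. The joint law of the look
#' statistics is multivariate normal with `corr(Z_j, Z_k) = sqrt(t_j / t_k)`;
#' for up to four looks the probability is computed by exact numerical
#' integration of the continuation density, beyond that by Monte Carlo
#' (with a warning).
#'
#' @param nominal_alphas Per-look two-sided nominal levels. A level of 0 is
#'   allowed and means that look can never reject.
#' @param fractions Strictly increasing information fractions, the last
#'   equal to 1, one per look.
#' @param ngrid Number of integration grid points per look (default 2001).
#' @param mc_reps Monte-Carlo replicates used when there are more than four
#'   looks (default 1e6).
#' @return The overall two-sided crossing probability under H0.
#' @examples
#' crossing_probability(0.05, 1)                      # single look: 0.05
#' crossing_probability(c(0, 0.03), c(0.5, 1))        # degenerate first look
#' @export
crossing_probability <- function(nominal_alphas, fractions, ngrid = 2001L,
                                 mc_reps = 1e6) {
  k <- length(nominal_alphas)
  if (length(fractions) != k)
    stop("nominal_alphas and fractions must have the same length.",
         call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions <= 0) ||
      any(fractions > 1) || any(diff(fractions) <= 0) ||
      abs(fractions[k] - 1) > 1e-12)
    stop("fractions must be strictly increasing in (0, 1] with last = 1.",
         call. = FALSE)
  if (any(nominal_alphas < 0) || any(nominal_alphas >= 1))
    stop("nominal alphas must lie in [0, 1).", call. = FALSE)
  crit <- stats::qnorm(1 - nominal_alphas / 2)  # Inf when alpha = 0
  if (k > 4L) {
    warning("more than 4 looks: falling back to Monte-Carlo integration.")
    return(mc_crossing(crit, fractions, mc_reps))
  }
  gs_crossing(crit, fractions, ngrid)
}

# Exact crossing probability by the continuation-density recursion on the
# score scale S_k = Z_k * sqrt(t_k), a Gaussian random walk with independent
# increments of variance t_k - t_{k-1}. Trapezoid rule on a uniform grid.
gs_crossing <- function(crit, fractions, ngrid = 2001L) {
  k <- length(crit)
  cap <- 10                                   # |z| cap: mass beyond ~1e-23
  b <- pmin(crit, cap) * sqrt(fractions)      # boundaries on the score scale
  sd1 <- sqrt(fractions[1])
  crossed <- 2 * stats::pnorm(-b[1], sd = sd1)
  if (k == 1L) return(crossed)
  x <- seq(-b[1], b[1], length.out = ngrid)
  w <- rep(x[2] - x[1], ngrid); w[c(1, ngrid)] <- w[1] / 2
  g <- stats::dnorm(x, sd = sd1) * w          # continuation measure at look 1
  for (j in 2:k) {
    sinc <- sqrt(fractions[j] - fractions[j - 1])
    # P(cross at look j) = sum over continuation states of exit probability
    crossed <- crossed + sum(g * (stats::pnorm((-b[j] - x) / sinc) +
                                  stats::pnorm((b[j] - x) / sinc,
                                               lower.tail = FALSE)))
    if (j < k) {
      y <- seq(-b[j], b[j], length.out = ngrid)
      wy <- rep(y[2] - y[1], ngrid); wy[c(1, ngrid)] <- wy[1] / 2
      g <- as.vector(stats::dnorm(outer(y, x, "-") / sinc) %*% g) / sinc * wy
      x <- y
    }
  }
  crossed
}

mc_crossing <- function(crit, fractions, reps) {
  k <- length(fractions)
  inc_sd <- sqrt(diff(c(0, fractions)))
  s <- matrix(stats::rnorm(reps * k), reps, k)
  s <- sweep(s, 2, inc_sd, "*")
  s <- t(apply(s, 1, cumsum))
  z <- sweep(s, 2, sqrt(fractions), "/")
  mean(apply(abs(z) >= rep(crit, each = reps), 1, any))
}

#' Nominal two-sided levels for a two-look design
#'
#' Computes per-look nominal significance levels for a design with one
#' interim at information fraction `t1` and a final analysis at full
#' information, such that the overall two-sided type-1 error equals
#' `alpha_total`.
#'
#' Two constructions are offered. `"ldof_spending"` spends
#' [of_spending_cumulative()]`(t1)` at the interim and solves for the final
#' nominal level so the joint crossing probability is exact.
#' `"classic_of"` uses the original O'Brien-Fleming boundary shape
#' `z_k = C / sqrt(t_k)` and solves for the constant `C`.
#'
#' @param t1 Interim information fraction, in (0, 1).
#' @param alpha_total Overall two-sided level (default 0.05).
#' @param method `"ldof_spending"` (default) or `"classic_of"`.
#' @return Named numeric vector `c(alpha_1, alpha_2)` of two-sided nominal
#'   levels for the interim and final look.
#' @examples
#' two_look_nominal_alphas(0.3, 0.05)
#' two_look_nominal_alphas(0.5, 0.05, method = "classic_of")
#' @export
two_look_nominal_alphas <- function(t1, alpha_total = 0.05,
                                    method = c("ldof_spending", "classic_of")) {
  method <- match.arg(method)
  check_alpha(alpha_total)
  if (!is.numeric(t1) || length(t1) != 1L || t1 <= 0 || t1 >= 1)
    stop("t1 must lie strictly between 0 and 1.", call. = FALSE)
  fractions <- c(t1, 1)
  if (method == "ldof_spending") {
    a1 <- of_spending_cumulative(t1, alpha_total)
    f <- function(a2) crossing_probability(c(a1, a2), fractions) - alpha_total
    sol <- stats::uniroot(f, lower = alpha_total / 4, upper = alpha_total,
                          tol = 1e-12)
    a2 <- sol$root
  } else {
    # boundary z_k = C / sqrt(t_k); solve C for exact overall alpha
    f <- function(cc) {
      a <- 2 * stats::pnorm(cc / sqrt(fractions), lower.tail = FALSE)
      crossing_probability(a, fractions) - alpha_total
    }
    cc <- stats::uniroot(f, lower = stats::qnorm(1 - alpha_total / 2),
                         upper = stats::qnorm(1 - alpha_total / 2) / sqrt(t1) + 2,
                         tol = 1e-12)$root
    a1 <- 2 * stats::pnorm(cc / sqrt(t1), lower.tail = FALSE)
    a2 <- 2 * stats::pnorm(cc, lower.tail = FALSE)
  }
  c(alpha_1 = a1, alpha_2 = a2)
}
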