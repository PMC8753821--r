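# Sequential allele-group budget planner.
#
# A fixed participant budget is spent on a series of test groups, each
# compared against a shared control arm. Each stage runs to a single interim
# at `interim_n` per group; a group that stops (futility or efficacy) has
# consumed `interim_n` participants, and the remaining budget is split
# equally between the control arm and the next test group. Stage k's final
# per-group size is therefore floor((total_n - interim_n * (k - 1)) / 2).

# Interim efficacy levels printed in the published three-stage design
# (interims at 15 of 50, 42, 35 per group). These are shipped as the default
# design constants; they are not reproduced by Lan-DeMets O'Brien-Fleming
# spending at those fractions (which gives ~3.5e-4 at t = 0.3), so the
# planner records the provenance of whichever levels it uses. See
# plan_design(efficacy_alpha_source).
printed_efficacy_alphas <- c(0.0013, 0.0023, 0.0055)

# Required interim effect sizes as printed in the same published schedule.
# The planner always emits its own computed values; these are attached as an
# annotation for comparison. Stage 2 is known to disagree: at alpha 0.0023
# the computed minimum detectable d at n = 15 is ~1.55, not the printed 1.52.
printed_interim_d <- c(1.63, 1.52, 1.42)

#' Global design parameters for an adaptive recall-by-genotype study
#'
#' Bundles the constants that define the sequential design: the total
#' participant budget, the per-group interim size, the endpoint standard
#' deviation, the final-test significance level, and the target power used
#' for both the futility rule and the interim efficacy effect sizes.
#'
#' @param total_n Total participant budget across all arms (default 100).
#' @param interim_n Per-group sample size at each interim look (default 15).
#' @param sd Endpoint standard deviation in degrees C (default 2.5, the
#'   reference-population spread of the heat pain threshold).
#' @param alpha_final Two-sided level of the final analysis (default 0.05).
#' @param power_target Power target for futility prediction and design
#'   effect sizes (default 0.80).
#' @param n_groups Number of sequential allele test groups (default 3).
#' @param efficacy_alphas Optional per-stage two-sided interim efficacy
#'   levels overriding the defaults; length `n_groups`.
#' @param strict_spending If `TRUE`, the final analysis of a stage is tested
#'   at `alpha_final` minus the alpha already spent at that stage's interim;
#'   if `FALSE` (default) the final test uses `alpha_final` unchanged.
#' @return An object of class `"rbg_design_params"` (a validated list).
#' @examples
#' design_params()
#' design_params(total_n = 80, interim_n = 10, n_groups = 2)
#' @export
design_params <- function(total_n = 100, interim_n = 15, sd = 2.5,
                          alpha_final = 0.05, power_target = 0.80,
                          n_groups = 3, efficacy_alphas = NULL,
                          strict_spending = FALSE) {
  check_alpha(alpha_final)
  check_power(power_target)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("sd must be a single positive number.", call. = FALSE)
  check_n_per_group(interim_n)
  if (!is.numeric(total_n) || length(total_n) != 1L || total_n != round(total_n))
    stop("total_n must be a single integer.", call. = FALSE)
  if (total_n < 2 * interim_n)
    stop("infeasible design: total_n (", total_n, ") cannot seat two groups ",
         "of interim_n (", interim_n, ").", call. = FALSE)
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 1 ||
      n_groups != round(n_groups))
    stop("n_groups must be a single integer >= 1.", call. = FALSE)
  if (!is.null(efficacy_alphas)) {
    if (length(efficacy_alphas) != n_groups)
      stop("efficacy_alphas must have one level per group (", n_groups, ").",
           call. = FALSE)
    for (a in efficacy_alphas) check_alpha(a)
  }
  structure(list(total_n = as.integer(total_n),
                 interim_n = as.integer(interim_n), sd = sd,
                 alpha_final = alpha_final, power_target = power_target,
                 n_groups = as.integer(n_groups),
                 efficacy_alphas = efficacy_alphas,
                 strict_spending = isTRUE(strict_spending)),
            class = "rbg_design_params")
}

#' @export
print.rbg_design_params <- function(x, ...) {
  cat("Adaptive RbG design parameters\n",
      "  budget (total_n):   ", x$total_n, "\n",
      "  interim per group:  ", x$interim_n, "\n",
      "  endpoint SD:        ", x$sd, " degC\n",
      "  final alpha:        ", x$alpha_final,
      if (x$strict_spending) " (strict spending)" else "", "\n",
      "  power target:       ", x$power_target, "\n",
      "  allele groups:      ", x$n_groups, "\n", sep = "")
  invisible(x)
}

#' Final per-group sample size at a given stage
#'
#' Stage `k` of the sequential design starts after `k - 1` test groups have
#' each consumed `interim_n` participants; the residual budget is split
#' equally between the control arm and the live test group, rounding down
#' to keep the groups equal:
#' `floor((total_n - interim_n * (k - 1)) / 2)`.
#'
#' @param params An [design_params()] object.
#' @param stage Stage index, from 1 to `params$n_groups`.
#' @return Integer final sample size per group for that stage.
#' @examples
#' p <- design_params()
#' sapply(1:3, function(k) final_n_per_group(p, k))  # 50 42 35
#' @export
final_n_per_group <- function(params, stage) {
  stopifnot(inherits(params, "rbg_design_params"))
  if (!is.numeric(stage) || length(stage) != 1L || stage < 1 ||
      stage > params$n_groups || stage != round(stage))
    stop("stage must be an integer between 1 and ", params$n_groups, ".",
         call. = FALSE)
  remainder <- params$total_n - params$interim_n * (stage - 1)
  if (remainder < 2 * params$interim_n)
    stop("infeasible stage ", stage, ": residual budget ", remainder,
         " cannot seat two groups of ", params$interim_n, ".", call. = FALSE)
  as.integer(floor(remainder / 2))
}

#' Build the full adaptive design schedule
#'
#' Derives, for each sequential allele-group stage: the final per-group
#' sample size under the budget rule, the interim information fraction, the
#' futility cutoff (the minimum detectable d at the stage's final size,
#' target power and final alpha), the interim efficacy level, and the
#' effect size (and its degrees-C equivalent) required to cross that
#' efficacy level at the interim with the target power.
#'
#' Efficacy levels come from, in order of precedence: the
#' `efficacy_alphas` field of `params` (provenance `"user"`); the published
#' three-stage design constants 0.0013 / 0.0023 / 0.0055 when
#' `efficacy_alpha_source = "printed"` and the design has at most three
#' groups (provenance `"printed"`); or the Lan-DeMets O'Brien-Fleming
#' spending function evaluated at each stage's information fraction
#' (provenance `"computed"`). The printed constants and the spending
#' computation do not coincide (spending at t = 0.3 gives ~3.5e-4, not
#' 0.0013); the `alpha_provenance` column records which was used.
#'
#' @inheritParams final_n_per_group
#' @param efficacy_alpha_source `"printed"` (default) or `"computed"`;
#'   ignored when `params$efficacy_alphas` is set.
#' @return A data frame of class `"rbg_design_plan"` with one row per
#'   stage and columns `stage`, `final_n_per_group`, `info_fraction`,
#'   `futility_d`, `futility_delta`, `efficacy_alpha`, `alpha_provenance`,
#'   `required_interim_d`, `required_interim_delta`. When the printed
#'   efficacy levels are used, the attribute `"published_interim_d"`
#'   carries the published schedule's rounded required interim effect
#'   sizes for comparison; the planner's own column is always the value it
#'   computed (stage 2 is known to differ: ~1.55 computed vs 1.52
#'   published).
#' @examples
#' plan_design(design_params())
#' @export
plan_design <- function(params = design_params(),
                        efficacy_alpha_source = c("printed", "computed")) {
  stopifnot(inherits(params, "rbg_design_params"))
  efficacy_alpha_source <- match.arg(efficacy_alpha_source)
  k <- seq_len(params$n_groups)
  n_final <- vapply(k, function(s) final_n_per_group(params, s), integer(1))
  frac <- params$interim_n / n_final
  futility_d <- vapply(n_final, minimum_detectable_d,
                       numeric(1), power = params$power_target,
                       alpha = params$alpha_final)
  if (!is.null(params$efficacy_alphas)) {
    eff_alpha <- params$efficacy_alphas
    provenance <- "user"
  } else if (efficacy_alpha_source == "printed") {
    if (params$n_groups > length(printed_efficacy_alphas))
      stop("printed efficacy levels exist for at most ",
           length(printed_efficacy_alphas), " stages; use ",
           "efficacy_alpha_source = \"computed\" or supply efficacy_alphas.",
           call. = FALSE)
    eff_alpha <- printed_efficacy_alphas[k]
    provenance <- "printed"
  } else {
    eff_alpha <- of_spending_cumulative(frac, params$alpha_final)
    provenance <- "computed"
  }
  req_d <- vapply(seq_along(k), function(i)
    minimum_detectable_d(params$interim_n, params$power_target, eff_alpha[i]),
    numeric(1))
  plan <- data.frame(stage = as.integer(k),
                     final_n_per_group = n_final,
                     info_fraction = frac,
                     futility_d = futility_d,
                     futility_delta = futility_d * params$sd,
                     efficacy_alpha = eff_alpha,
                     alpha_provenance = provenance,
                     required_interim_d = req_d,
                     required_interim_delta = req_d * params$sd)
  bad <- plan$futility_d >= plan$required_interim_d
  if (any(bad))
    stop("planning error: futility cutoff meets or exceeds the required ",
         "interim effect at stage(s) ", paste(which(bad), collapse = ", "),
         "; the interim efficacy levels are too lax for this budget.",
         call. = FALSE)
  class(plan) <- c("rbg_design_plan", "data.frame")
  attr(plan, "params") <- params
  if (provenance == "printed")
    attr(plan, "published_interim_d") <- printed_interim_d[k]
  plan
}

#' @export
print.rbg_design_plan <- function(x, ...) {
  cat("Adaptive RbG design schedule (one row per allele-group stage)\n")
  print(design_table(x), row.names = FALSE)
  cat("futility/effect sizes are Cohen's d; deltas assume endpoint SD ",
      attr(x, "params")$sd, " degC\n", sep = "")
  invisible(x)
}
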