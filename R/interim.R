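# Pre-specified interim and final analysis.
#
# At an interim the observed standardized effect is plugged into the exact
# power function at the stage's *final* sample size: if the predicted power
# falls short of the target the group stops for futility; otherwise a
# hypothesis test at the stage's interim efficacy level decides between
# stopping for efficacy and continuing to the planned end.

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(mean(test) - mean(control)) / s_p` where
#' `s_p` is the Bessel-corrected pooled standard deviation. No small-sample
#' (Hedges) correction is applied.
#'
#' @param test,control Numeric vectors of endpoint measurements, at least
#'   two finite values each.
#' @return A list with elements `d` (signed, test minus control) and
#'   `pooled_sd`.
#' @examples
#' cohens_d(c(3, 4, 5), c(1, 2, 3))  # d = 2, pooled sd = 1
#' @export
cohens_d <- function(test, control) {
  check_group(test, "test"); check_group(control, "control")
  n1 <- length(test); n2 <- length(control)
  sp <- sqrt(((n1 - 1) * stats::var(test) + (n2 - 1) * stats::var(control)) /
               (n1 + n2 - 2))
  if (sp == 0)
    stop("effect size undefined: pooled standard deviation is zero.",
         call. = FALSE)
  list(d = (mean(test) - mean(control)) / sp, pooled_sd = sp)
}

check_group <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)))
    stop(name, " group needs at least 2 finite endpoint values.",
         call. = FALSE)
  invisible(x)
}

#' Interim futility/efficacy decision for one allele-group stage
#'
#' Implements the pre-specified interim rule. The observed Cohen's d is
#' computed from the interim samples; predicted power is the exact
#' noncentral-t power of |d| at the stage's final per-group size and the
#' final-test alpha. If predicted power is below the target the decision is
#' `stop_futility`. Otherwise a two-sided pooled t-test is performed: if its
#' p-value is at or below the stage's interim efficacy level the decision is
#' `stop_efficacy`, else `continue`. Predicted power exactly equal to the
#' target counts as adequate (the rule reads "predicts >= 80%").
#'
#' The futility branch is equivalent (to root-finder tolerance) to comparing
#' |d| against the stage's `futility_d` cutoff.
#'
#' @inheritParams cohens_d
#' @param stage_plan One row of a [plan_design()] schedule (or the schedule
#'   plus `stage` to pick the row).
#' @param params The [design_params()] object that produced the plan;
#'   defaults to the plan's own attribute.
#' @param stage Stage index used when `stage_plan` is a full schedule.
#' @param welch If `TRUE` use the Welch (unequal-variance) t-test for the
#'   efficacy p-value instead of the pooled test. Design numbers always use
#'   the pooled test; the flag exists for sensitivity analysis only.
#' @return An object of class `"rbg_interim_result"`: a list with
#'   `observed_d`, `pooled_sd`, `predicted_power`, `p_value`, `decision`
#'   (one of `"continue"`, `"stop_futility"`, `"stop_efficacy"`) and
#'   `stage`.
#' @examples
#' plan <- plan_design(design_params())
#' set.seed(1)
#' interim_decide(rnorm(15, 46, 2.5), rnorm(15, 42, 2.5), plan, stage = 1)
#' @export
interim_decide <- function(test, control, stage_plan, params = NULL,
                           stage = NULL, welch = FALSE) {
  row <- resolve_stage(stage_plan, stage)
  if (is.null(params)) params <- attr(stage_plan, "params")
  if (is.null(params))
    stop("params must be supplied when stage_plan carries no design ",
         "parameters.", call. = FALSE)
  if (length(test) < params$interim_n || length(control) < params$interim_n)
    stop("configuration error: each group needs at least interim_n = ",
         params$interim_n, " observations for the stage-", row$stage,
         " interim.", call. = FALSE)
  if (length(test) > params$interim_n || length(control) > params$interim_n)
    warning("interim samples exceed interim_n = ", params$interim_n,
            "; using all supplied observations.")
  eff <- cohens_d(test, control)
  predicted_power <- power_t2(abs(eff$d), row$final_n_per_group,
                              params$alpha_final)
  p <- stats::t.test(test, control, var.equal = !welch)$p.value
  decision <- if (predicted_power < params$power_target) {
    "stop_futility"
  } else if (p <= row$efficacy_alpha) {
    "stop_efficacy"
  } else {
    "continue"
  }
  structure(list(observed_d = eff$d, pooled_sd = eff$pooled_sd,
                 predicted_power = predicted_power, p_value = p,
                 decision = decision, stage = row$stage,
                 n_test = length(test), n_control = length(control)),
            class = "rbg_interim_result")
}

#' @export
print.rbg_interim_result <- function(x, ...) {
  cat("Interim analysis, stage ", x$stage, " (n = ", x$n_test, " vs ",
      x$n_control, ")\n",
      "  observed d:      ", sprintf("%+.3f", x$observed_d),
      "  (pooled SD ", sprintf("%.3f", x$pooled_sd), ")\n",
      "  predicted power: ", sprintf("%.3f", x$predicted_power), "\n",
      "  p-value:         ", format.pval(x$p_value, digits = 3), "\n",
      "  decision:        ", x$decision, "\n", sep = "")
  invisible(x)
}

#' Interim decision from summary statistics
#'
#' Entry point mirroring [interim_decide()] for when only group summaries
#' (size, mean, SD) are available rather than participant-level data.
#'
#' @param n_test,mean_test,sd_test Size, mean and SD of the test group.
#' @param n_control,mean_control,sd_control Same for the control group.
#' @inheritParams interim_decide
#' @return An `"rbg_interim_result"`, as for [interim_decide()].
#' @export
interim_decide_stats <- function(n_test, mean_test, sd_test,
                                 n_control, mean_control, sd_control,
                                 stage_plan, params = NULL, stage = NULL) {
  row <- resolve_stage(stage_plan, stage)
  if (is.null(params)) params <- attr(stage_plan, "params")
  if (is.null(params)) stop("params required.", call. = FALSE)
  if (n_test < 2 || n_control < 2)
    stop("each group needs n >= 2.", call. = FALSE)
  df <- n_test + n_control - 2
  sp <- sqrt(((n_test - 1) * sd_test^2 + (n_control - 1) * sd_control^2) / df)
  if (sp == 0) stop("pooled standard deviation is zero.", call. = FALSE)
  d <- (mean_test - mean_control) / sp
  tstat <- (mean_test - mean_control) /
    (sp * sqrt(1 / n_test + 1 / n_control))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  predicted_power <- power_t2(abs(d), row$final_n_per_group,
                              params$alpha_final)
  decision <- if (predicted_power < params$power_target) "stop_futility"
    else if (p <= row$efficacy_alpha) "stop_efficacy" else "continue"
  structure(list(observed_d = d, pooled_sd = sp,
                 predicted_power = predicted_power, p_value = p,
                 decision = decision, stage = row$stage,
                 n_test = n_test, n_control = n_control),
            class = "rbg_interim_result")
}

#' Final analysis of a completed stage
#'
#' Two-sided pooled-variance t-test of test versus control at the final
#' sample size. In the default mode significance is declared at
#' `alpha_final`; in strict-spending mode the level is reduced by the alpha
#' already spent at the stage's interim.
#'
#' @inheritParams interim_decide
#' @param stage_plan Optional stage row; needed only for strict-spending
#'   mode (to know the interim alpha spent).
#' @return List with `p_value`, `significant`, and `alpha_used`.
#' @examples
#' p <- design_params()
#' set.seed(1)
#' final_analyze(rnorm(50, 43.5, 2.5), rnorm(50, 42, 2.5), p)
#' @export
final_analyze <- function(test, control, params, stage_plan = NULL,
                          stage = NULL, welch = FALSE) {
  stopifnot(inherits(params, "rbg_design_params"))
  check_group(test, "test"); check_group(control, "control")
  alpha_used <- params$alpha_final
  if (params$strict_spending) {
    if (is.null(stage_plan))
      stop("strict-spending mode needs the stage plan to know the interim ",
           "alpha spent.", call. = FALSE)
    row <- resolve_stage(stage_plan, stage)
    alpha_used <- params$alpha_final - row$efficacy_alpha
  }
  if (stats::sd(test) == 0 && stats::sd(control) == 0)
    stop("final analysis undefined: both groups are constant.", call. = FALSE)
  p <- stats::t.test(test, control, var.equal = !welch)$p.value
  list(p_value = p, significant = p <= alpha_used, alpha_used = alpha_used)
}

#' Read group samples from a participant-level CSV
#'
#' Reads an interim/final data export with columns `participant_id`,
#' `group` (values `"test"` and `"control"`) and `endpoint` (numeric, degC),
#' and returns the two endpoint vectors. This is the decision engine's
#' data interface: it carries group labels and endpoint values only, never
#' genotypes, so analysts using it stay blind to genotype.
#'
#' @param path Path to the CSV file.
#' @return List with numeric vectors `test` and `control`.
#' @export
read_group_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "endpoint")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$group %in% c("test", "control")))
    stop("group column must contain only \"test\" and \"control\".",
         call. = FALSE)
  list(test = as.numeric(df$endpoint[df$group == "test"]),
       control = as.numeric(df$endpoint[df$group == "control"]))
}

resolve_stage <- function(stage_plan, stage = NULL) {
  if (inherits(stage_plan, "rbg_design_plan") || (is.data.frame(stage_plan) &&
      nrow(stage_plan) > 1)) {
    if (nrow(stage_plan) > 1) {
      if (is.null(stage))
        stop("supply stage = k to pick a row of the design plan.",
             call. = FALSE)
      i <- match(stage, stage_plan$stage)
      if (is.na(i))
        stop("configuration error: plan has no stage ", stage, ".",
             call. = FALSE)
      return(stage_plan[i, , drop = FALSE])
    }
  }
  if (!is.data.frame(stage_plan) || nrow(stage_plan) != 1L)
    stop("stage_plan must be a design-plan row.", call. = FALSE)
  if (!is.null(stage) && stage_plan$stage != stage)
    stop("configuration error: data are for stage ", stage,
         " but the plan row is stage ", stage_plan$stage, ".", call. = FALSE)
  stage_plan
}
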