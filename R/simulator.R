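# Monte-Carlo engine for the interim rule's operating characteristics.
#
# Each replicate draws a complete trial (final size per group) on the
# standardized scale — control N(0, 1), test N(d, 1) — applies the interim
# rule to the first interim_n observations per group, runs the final
# analysis on the full data, and classifies the interim call against the
# final outcome. Decisions are scale-equivariant, so results on the d scale
# apply unchanged to endpoints in degrees C.

#' Simulate the interim rule at a fixed true effect size
#'
#' @param true_d True standardized effect size of the test group.
#' @param params [design_params()] object.
#' @param stage Which stage's plan row to use (default 1).
#' @param interim_n Interim size per group; defaults to `params$interim_n`
#'   but can be varied for interim-timing studies.
#' @param reps Number of replicate trials (default 10000).
#' @param seed Optional RNG seed for reproducibility.
#' @param efficacy_rule If `TRUE` (default) the interim applies both the
#'   futility and the efficacy test; if `FALSE`, futility only (an interim
#'   that passes futility always continues).
#' @param boot_resample,boot_reps Bootstrap settings for the confidence
#'   intervals: `boot_reps` resamples of `boot_resample` replicate outcomes
#'   (default 100 outcomes, 1000 resamples).
#' @param plan Optional pre-computed design plan (saves recomputation in
#'   sweeps).
#' @param sd Endpoint standard deviation for the draws (default 1, the
#'   standardized scale). Decisions are invariant to this scale.
#' @return An object of class `"rbg_sim_summary"`: a list with the
#'   decision rates (`halt`, `continue`, `stop_efficacy`), the
#'   misclassification rates against the completed trial
#'   (`false_negative_halt`: halted although the full trial would have been
#'   significant; `false_positive_continue`: continued although it would
#'   not), `correct_decision` with bootstrap 95% CI, and the settings used.
#' @examples
#' simulate_fixed_effect(1.6, design_params(), reps = 2000, seed = 1)
#' @export
simulate_fixed_effect <- function(true_d, params = design_params(),
                                  stage = 1, interim_n = params$interim_n,
                                  reps = 10000, seed = NULL,
                                  efficacy_rule = TRUE,
                                  boot_resample = 100, boot_reps = 1000,
                                  plan = NULL, sd = 1) {
  stopifnot(inherits(params, "rbg_design_params"), reps >= 1)
  if (is.null(plan)) plan <- plan_design(params)
  row <- resolve_stage(plan, stage)
  n_final <- row$final_n_per_group
  if (interim_n > n_final)
    stop("interim_n (", interim_n, ") exceeds the stage's final size (",
         n_final, ").", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- matrix(stats::rnorm(reps * n_final, 0, sd), reps, n_final)
  test <- matrix(stats::rnorm(reps * n_final, true_d * sd, sd), reps, n_final)
  intr <- two_sample_t_rows(test[, seq_len(interim_n), drop = FALSE],
                            ctrl[, seq_len(interim_n), drop = FALSE])
  fin <- two_sample_t_rows(test, ctrl)
  predicted_power <- power_t2_vec(abs(intr$d), n_final, params$alpha_final)
  halt <- predicted_power < params$power_target
  stop_eff <- if (efficacy_rule) !halt & intr$p <= row$efficacy_alpha
              else rep(FALSE, reps)
  cont <- !halt & !stop_eff
  final_sig <- fin$p <= params$alpha_final
  # a halt is correct iff the completed trial would NOT have been
  # significant; a pass (continue or efficacy stop) is correct iff it would
  correct <- ifelse(halt, !final_sig, final_sig)
  ci <- boot_ci(correct, boot_resample, boot_reps)
  structure(list(true_d = true_d, interim_n = interim_n, stage = row$stage,
                 n_final_per_group = n_final, reps = reps,
                 efficacy_rule = efficacy_rule,
                 rates = c(halt = mean(halt), continue = mean(cont),
                           stop_efficacy = mean(stop_eff)),
                 false_negative_halt = mean(halt & final_sig),
                 false_positive_continue = mean(cont & !final_sig),
                 correct_decision = mean(correct),
                 correct_ci = ci,
                 final_significant = mean(final_sig)),
            class = "rbg_sim_summary")
}

#' @export
print.rbg_sim_summary <- function(x, ...) {
  cat("Interim-rule operating characteristics (", x$reps, " replicates)\n",
      "  true d ", x$true_d, ", interim n ", x$interim_n, " of ",
      x$n_final_per_group, " per group\n", sep = "")
  cat(sprintf("  halt %.3f | continue %.3f | stop_efficacy %.3f\n",
              x$rates["halt"], x$rates["continue"], x$rates["stop_efficacy"]))
  cat(sprintf("  correct decision %.3f (95%% CI %.3f-%.3f)\n",
              x$correct_decision, x$correct_ci[1], x$correct_ci[2]))
  cat(sprintf("  false-negative halt %.3f | false-positive continue %.3f\n",
              x$false_negative_halt, x$false_positive_continue))
  invisible(x)
}

#' Sweep the interim size to choose its timing
#'
#' Runs [simulate_fixed_effect()] over a grid of interim sizes and effect
#' sizes and tabulates the correct-decision percentage with its bootstrap
#' CI and the marginal gain per added interim participant — the quantities
#' used to pick the interim timing (the gain flattens once the interim is
#' informative enough).
#'
#' @param interim_n_grid Integer vector of interim sizes to evaluate.
#' @param true_ds Effect sizes to evaluate (default `c(0, 0.6)`: the null
#'   and the minimum clinically relevant effect).
#' @inheritParams simulate_fixed_effect
#' @return Long-format data frame: `interim_n`, `true_d`, `correct_pct`,
#'   `ci_lo`, `ci_hi`, `marginal_gain_pct` (change in correct % per added
#'   participant relative to the previous grid point; `NA` for the first).
#' @export
interim_timing_sweep <- function(interim_n_grid, true_ds = c(0, 0.6),
                                 params = design_params(), stage = 1,
                                 reps = 10000, seed = NULL,
                                 efficacy_rule = TRUE,
                                 boot_resample = 100, boot_reps = 1000) {
  if (length(interim_n_grid) < 1) stop("interim_n_grid is empty.",
                                       call. = FALSE)
  interim_n_grid <- sort(unique(as.integer(interim_n_grid)))
  if (!is.null(seed)) set.seed(seed)
  plan <- plan_design(params)
  out <- list()
  for (d in true_ds) {
    prev <- NULL; prev_n <- NULL
    for (m in interim_n_grid) {
      s <- simulate_fixed_effect(d, params, stage, interim_n = m, reps = reps,
                                 efficacy_rule = efficacy_rule,
                                 boot_resample = boot_resample,
                                 boot_reps = boot_reps, plan = plan)
      gain <- if (is.null(prev)) NA_real_ else
        100 * (s$correct_decision - prev) / (m - prev_n)
      out[[length(out) + 1L]] <- data.frame(
        interim_n = m, true_d = d,
        correct_pct = 100 * s$correct_decision,
        ci_lo = 100 * s$correct_ci[1], ci_hi = 100 * s$correct_ci[2],
        marginal_gain_pct = gain)
      prev <- s$correct_decision; prev_n <- m
    }
  }
  do.call(rbind, out)
}

#' Simulate the full sequential adaptive study
#'
#' Simulates the whole multi-group pathway: each allele group runs to its
#' stage's interim; on futility or efficacy the group stops (having
#' consumed `interim_n` participants) and the next group starts; on
#' continue, the stage runs to its final size and the study ends with the
#' final analysis. Budget bookkeeping follows the planner's rule, so total
#' consumption never exceeds `total_n`.
#'
#' @param params [design_params()] object.
#' @param true_ds True standardized effect size per allele group (length
#'   `params$n_groups`).
#' @param reps Number of simulated studies (default 1000).
#' @param seed Optional RNG seed.
#' @return A list with `pathways` (frequency table of pathway strings such
#'   as `"futility>efficacy"`), `group_decisions` (per-group decision
#'   proportions; groups never reached count as `not_reached`),
#'   `final_significant_rate` (among pathways ending in a completed final
#'   analysis), `mean_consumed`, and `max_consumed`.
#' @examples
#' simulate_adaptive_study(design_params(), c(0, 0, 0), reps = 200, seed = 1)
#' @export
simulate_adaptive_study <- function(params = design_params(), true_ds,
                                    reps = 1000, seed = NULL) {
  stopifnot(inherits(params, "rbg_design_params"))
  if (length(true_ds) != params$n_groups)
    stop("true_ds must give one effect size per group (",
         params$n_groups, ").", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  plan <- plan_design(params)
  m <- params$interim_n
  decisions <- matrix(NA_character_, reps, params$n_groups)
  consumed <- numeric(reps)
  final_sig <- rep(NA, reps)
  pathway <- character(reps)
  for (r in seq_len(reps)) {
    spent_groups <- 0L
    steps <- character(0)
    for (k in seq_len(params$n_groups)) {
      row <- plan[k, ]
      n_final <- row$final_n_per_group
      test <- stats::rnorm(n_final, true_ds[k])
      ctrl <- stats::rnorm(n_final)
      res <- interim_decide(test[seq_len(m)], ctrl[seq_len(m)], row,
                            params = params)
      decisions[r, k] <- res$decision
      if (res$decision == "continue") {
        fin <- final_analyze(test, ctrl, params,
                             stage_plan = if (params$strict_spending) row)
        final_sig[r] <- fin$significant
        consumed[r] <- m * (k - 1) + 2 * n_final
        steps <- c(steps, "continue")
        break
      }
      steps <- c(steps, sub("stop_", "", res$decision))
      spent_groups <- k
      if (k == params$n_groups)
        consumed[r] <- m * params$n_groups + m  # all test groups + control
    }
    pathway[r] <- paste(steps, collapse = ">")
  }
  group_decisions <- apply(decisions, 2, function(col) {
    col[is.na(col)] <- "not_reached"
    prop.table(table(factor(col, levels = c("continue", "stop_futility",
                                            "stop_efficacy", "not_reached"))))
  })
  colnames(group_decisions) <- paste0("group", seq_len(params$n_groups))
  list(pathways = sort(table(pathway), decreasing = TRUE) / reps,
       group_decisions = group_decisions,
       final_significant_rate = mean(final_sig, na.rm = TRUE),
       mean_consumed = mean(consumed),
       max_consumed = max(consumed))
}

# ---- vectorized internals --------------------------------------------------

# row-wise pooled two-sample t-test on matrices (rows = replicates)
two_sample_t_rows <- function(test, ctrl) {
  n1 <- ncol(test); n2 <- ncol(ctrl)
  m1 <- rowMeans(test); m2 <- rowMeans(ctrl)
  v1 <- (rowSums(test^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(ctrl^2) - n2 * m2^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df)
  tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(d = (m1 - m2) / sp,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

# vectorized-in-d power (argument checks done once by callers)
power_t2_vec <- function(d, n_per_group, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- abs(d) * sqrt(n_per_group / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

# percentile bootstrap CI for a mean of 0/1 outcomes, resampling
# `resample` outcomes `reps` times
boot_ci <- function(x, resample = 100, reps = 1000, level = 0.95) {
  means <- vapply(seq_len(reps),
                  function(i) mean(x[sample.int(length(x), resample,
                                                replace = TRUE)]),
                  numeric(1))
  stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}
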