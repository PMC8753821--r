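# Configuration, pipeline orchestration and result serialization.
#
# A single YAML or JSON configuration drives planning, cohort synthesis,
# interim decisions and simulation; all randomness flows through the seed
# recorded in the run manifest, and every JSON artifact carries the run id
# of the manifest that produced it.

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON (detected by extension) with keys `total_n`,
#' `interim_n`, `sd`, `alpha_final`, `power_target`, `groups` (list of
#' `name`, `snps`, `maf`, `r2` entries), `efficacy_alphas`, `simulation`
#' (`reps`, `true_d`, `interim_n_grid`), and `cohort` (`pool_n`,
#' `group_sizes`, `effect_map`). All keys are optional; defaults are the
#' package's standard design.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list, validated against the recognised keys.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
  known <- c("total_n", "interim_n", "sd", "alpha_final", "power_target",
             "n_groups", "efficacy_alphas", "strict_spending", "groups",
             "simulation", "cohort")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("config error: unrecognised key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}

config_to_params <- function(cfg) {
  args <- cfg[intersect(names(cfg),
                        c("total_n", "interim_n", "sd", "alpha_final",
                          "power_target", "n_groups", "efficacy_alphas",
                          "strict_spending"))]
  if (is.null(args$n_groups) && !is.null(cfg$groups))
    args$n_groups <- length(cfg$groups)
  do.call(design_params, args)
}

#' Run the full design pipeline
#'
#' Plans the schedule, synthesizes a cohort, applies the stage-1 interim
#' decision to it, and runs the fixed-effect simulation, writing
#' `schedule.json`, `schedule.csv`, `cohort.csv`, `decision.json`,
#' `simulation.csv` and `manifest.json` under `out_dir`. Outputs are
#' deterministic given `seed`.
#'
#' @param config Configuration list (from [read_config()]) or a path to a
#'   config file. `NULL` uses all defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) config <- list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_to_params(config)
  plan <- plan_design(params)

  run_id <- sprintf("rbgadapt-%s-seed%d",
                    format(Sys.time(), "%Y%m%dT%H%M%S"), seed)
  paths <- c(schedule = file.path(out_dir, "schedule.json"),
             schedule_csv = file.path(out_dir, "schedule.csv"),
             cohort = file.path(out_dir, "cohort.csv"),
             decision = file.path(out_dir, "decision.json"),
             simulation = file.path(out_dir, "simulation.csv"),
             manifest = file.path(out_dir, "manifest.json"))

  jsonlite::write_json(
    list(run_id = run_id, stages = plan[setdiff(names(plan), NULL)]),
    paths[["schedule"]], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(design_table(plan), paths[["schedule_csv"]],
                   row.names = FALSE)

  coh_cfg <- utils::modifyList(
    list(pool_n = 8000,
         group_sizes = c(control = params$interim_n,
                         group1 = params$interim_n),
         effect_map = c(group1 = 0)),
    if (is.null(config$cohort)) list() else config$cohort)
  cohort <- synthesize_cohort(pool_n = coh_cfg$pool_n,
                              group_sizes = unlist(coh_cfg$group_sizes),
                              effect_map = unlist(coh_cfg$effect_map),
                              seed = seed)
  write_cohort_csv(cohort, paths[["cohort"]])

  test_lbl <- setdiff(unique(cohort$recall_group), "control")[1]
  res <- interim_decide(cohort$hpt_post[cohort$recall_group == test_lbl],
                        cohort$hpt_post[cohort$recall_group == "control"],
                        plan, params = params, stage = 1)
  jsonlite::write_json(c(list(run_id = run_id), unclass(res)),
                       paths[["decision"]], auto_unbox = TRUE, digits = NA)

  sim_cfg <- utils::modifyList(list(reps = 2000, true_d = c(0, 0.6, 1.6)),
                               if (is.null(config$simulation)) list()
                               else config$simulation)
  sims <- lapply(sim_cfg$true_d, function(d)
    simulate_fixed_effect(d, params, reps = sim_cfg$reps, plan = plan,
                          seed = seed + round(1000 * d)))
  utils::write.csv(oc_table(sims), paths[["simulation"]], row.names = FALSE)

  manifest <- list(run_id = run_id, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("rbgadapt")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config,
                   params = unclass(params),
                   alpha_provenance = unique(plan$alpha_provenance),
                   outputs = as.list(basename(paths)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(as.list(paths))
}

#' Render a design schedule as a display table
#'
#' Display rounding follows the design's reporting convention: effect
#' sizes (Cohen's d) to 2 decimal places, temperature differences to 1.
#'
#' @param plan A [plan_design()] schedule.
#' @return Data frame with columns `interim`, `futility_d`,
#'   `efficacy_alpha`, `required_interim_d` (formatted as
#'   `"d (delta degC)"`), `alpha_provenance`.
#' @examples
#' design_table(plan_design(design_params()))
#' @export
design_table <- function(plan) {
  stopifnot(is.data.frame(plan))
  data.frame(interim = plan$stage,
             final_n_per_group = plan$final_n_per_group,
             futility_d = sprintf("%.2f", plan$futility_d),
             efficacy_alpha = format(plan$efficacy_alpha, digits = 4),
             required_interim_d = sprintf("%.2f (Δ%.1f °C)",
                                          plan$required_interim_d,
                                          plan$required_interim_delta),
             alpha_provenance = plan$alpha_provenance)
}

#' Tabulate operating characteristics from simulation summaries
#'
#' Collects one or more [simulate_fixed_effect()] results into a long
#' table suitable for CSV export: one row per (interim_n, true_d, metric)
#' with value and bootstrap CI where available.
#'
#' @param sims A single `"rbg_sim_summary"` or a list of them (possibly
#'   empty: then a zero-row table with the documented header).
#' @return Long-format data frame: `interim_n`, `true_d`, `metric`,
#'   `value`, `ci_lo`, `ci_hi`.
#' @export
oc_table <- function(sims) {
  if (inherits(sims, "rbg_sim_summary")) sims <- list(sims)
  header <- data.frame(interim_n = integer(), true_d = numeric(),
                       metric = character(), value = numeric(),
                       ci_lo = numeric(), ci_hi = numeric())
  if (length(sims) == 0) return(header)
  rows <- lapply(sims, function(s) {
    metrics <- c(s$rates, false_negative_halt = s$false_negative_halt,
                 false_positive_continue = s$false_positive_continue,
                 correct_decision = s$correct_decision)
    data.frame(interim_n = s$interim_n, true_d = s$true_d,
               metric = names(metrics), value = unname(metrics),
               ci_lo = ifelse(names(metrics) == "correct_decision",
                              s$correct_ci[1], NA_real_),
               ci_hi = ifelse(names(metrics) == "correct_decision",
                              s$correct_ci[2], NA_real_))
  })
  do.call(rbind, rows)
}
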