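#' Run one pipeline stage and write its artifacts
#'
#' Ties the analysis stages together behind a single entry point (also used
#' by the shipped command-line script, `inst/cli/markov_cea.R`):
#' \describe{
#'   \item{`simulate`}{generate a synthetic patient cohort from the config's
#'     `cohort` block (defaults derived from the strategy blocks) and write
#'     `cohort.csv` plus `cohort_summary.csv`.}
#'   \item{`run`}{run the deterministic model: per-strategy transition
#'     tables (`transitions_<label>.csv`), traces (`trace_<label>.csv`), a
#'     cost-effectiveness table (`results.csv`) and `summary.json`.}
#'   \item{`tornado`}{one-way sensitivity analysis to `tornado.csv`.}
#'   \item{`psa`}{probabilistic sensitivity analysis to `psa_draws.csv` and
#'     `ceac.csv`.}
#'   \item{`report`}{collate previously written artifacts into `report.txt`;
#'     errors if `run` has not been executed.}
#' }
#' Identical configuration and seed produce identical artifacts.
#'
#' @param config A `cea_config` from [load_config()].
#' @param command One of `"simulate"`, `"run"`, `"tornado"`, `"psa"`,
#'   `"report"`.
#' @param out_dir Output directory; created if absent.
#' @param seed Optional integer overriding the configured sensitivity seed.
#' @param quiet Suppress progress messages; default `FALSE`.
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_pipeline <- function(config,
                         command = c("run", "simulate", "tornado", "psa",
                                     "report"),
                         out_dir = ".", seed = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "cea_config"))
  command <- match.arg(command)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seed <- if (is.null(seed)) config$sensitivity$seed else as.integer(seed)
  say <- function(...) if (!quiet) message("[pdcea] ", sprintf(...))
  say("stage %s (seed %d, package %s)", command, seed,
      as.character(packageVersion("pdcea")))
  paths <- switch(
    command,
    simulate = pipeline_simulate(config, out_dir, seed),
    run = pipeline_run(config, out_dir),
    tornado = pipeline_tornado(config, out_dir),
    psa = pipeline_psa(config, out_dir, seed),
    report = pipeline_report(out_dir)
  )
  say("wrote %s", paste(basename(paths), collapse = ", "))
  invisible(paths)
}

# cohort config resolved from the config's cohort block; survival and cost
# defaults fall back to the strategy blocks (post-progression median =
# median_os - median_dfs, cost mean = initial cost)
cohort_from_config <- function(config, seed) {
  co <- config$cohort
  s <- list(config$reference, config$comparator)
  cohort_config(
    arms = vapply(s, `[[`, "", "label"),
    n_per_arm = co$n_per_arm %||% 100,
    median_dfs = co$median_dfs %||% vapply(s, `[[`, 0, "median_dfs"),
    median_os = co$median_os %||% vapply(s, `[[`, 0, "median_os"),
    median_pps = co$median_pps,
    cost_mean = co$cost_mean %||% vapply(s, `[[`, 0, "initial_cost"),
    cost_cv = co$cost_cv %||% 0.3,
    accrual_window = co$accrual_window %||% 45,
    followup_cutoff = co$followup_cutoff %||% 87,
    seed = seed
  )
}

pipeline_simulate <- function(config, out_dir, seed) {
  records <- generate_cohort(cohort_from_config(config, seed))
  p1 <- file.path(out_dir, "cohort.csv")
  write_cohort(records, p1)
  p2 <- file.path(out_dir, "cohort_summary.csv")
  write.csv(summarize_cohort(records), p2, row.names = FALSE)
  c(p1, p2)
}

pipeline_run <- function(config, out_dir) {
  res <- run_cea(config)
  paths <- character(0)
  for (side in c("reference", "comparator")) {
    label <- res[[side]]$params$label
    pt <- file.path(out_dir, paste0("transitions_", label, ".csv"))
    write.csv(transition_table(res[[side]]$matrix,
                               fraction = config$sensitivity$fraction),
              pt, row.names = FALSE)
    ptr <- file.path(out_dir, paste0("trace_", label, ".csv"))
    write_trace(res[[side]]$trace, ptr)
    paths <- c(paths, pt, ptr)
  }
  tab <- data.frame(
    strategy = c(res$reference$econ$label, res$comparator$econ$label),
    cumulative_cost = round(c(res$reference$econ$total_cost,
                              res$comparator$econ$total_cost), 2),
    effects_qalys = round(c(res$reference$econ$total_qalys,
                            res$comparator$econ$total_qalys), 3),
    incremental_cost = c(NA, round(res$ce$delta_cost, 2)),
    incremental_effects = c(NA, round(res$ce$delta_effect, 3)),
    icer = c(NA, round(res$ce$icer, 2))
  )
  pr <- file.path(out_dir, "results.csv")
  write.csv(tab, pr, row.names = FALSE)
  ps <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(reference = list(strategy = res$reference$econ$label,
                          total_cost = res$reference$econ$total_cost,
                          total_qalys = res$reference$econ$total_qalys),
         comparator = list(strategy = res$comparator$econ$label,
                           total_cost = res$comparator$econ$total_cost,
                           total_qalys = res$comparator$econ$total_qalys),
         delta_cost = res$ce$delta_cost, delta_effect = res$ce$delta_effect,
         icer = res$ce$icer, decision = res$ce$decision, wtp = res$ce$wtp),
    ps, auto_unbox = TRUE, digits = NA)
  c(paths, pr, ps)
}

pipeline_strategies <- function(config) {
  ref <- resolve_strategy(config$reference, config$discount, config$n_cycles,
                          config$half_cycle)
  cmp <- resolve_strategy(config$comparator, config$discount, config$n_cycles,
                          config$half_cycle)
  list(reference = ref$params, comparator = cmp$params)
}

pipeline_tornado <- function(config, out_dir) {
  s <- pipeline_strategies(config)
  tor <- one_way_tornado(s$reference, s$comparator, config$wtp,
                         n_cycles = config$n_cycles,
                         fraction = config$sensitivity$fraction,
                         half_cycle = config$half_cycle)
  p <- file.path(out_dir, "tornado.csv")
  write.csv(as.data.frame(tor), p, row.names = FALSE)
  p
}

pipeline_psa <- function(config, out_dir, seed) {
  s <- pipeline_strategies(config)
  ps <- psa(s$reference, s$comparator, config$wtp,
            n_cycles = config$n_cycles,
            n_draws = config$sensitivity$n_draws,
            fraction = config$sensitivity$fraction, seed = seed,
            distributions = config$sensitivity$distributions,
            half_cycle = config$half_cycle)
  p1 <- file.path(out_dir, "psa_draws.csv")
  write.csv(ps$draws, p1, row.names = FALSE)
  p2 <- file.path(out_dir, "ceac.csv")
  write.csv(as.data.frame(ceac(ps)), p2, row.names = FALSE)
  c(p1, p2)
}

pipeline_report <- function(out_dir) {
  summary_path <- file.path(out_dir, "summary.json")
  if (!file.exists(summary_path)) {
    stop("no `summary.json` in ", out_dir,
         ": run the `run` stage before `report`", call. = FALSE)
  }
  s <- jsonlite::read_json(summary_path, simplifyVector = TRUE)
  lines <- c(
    "Cost-effectiveness analysis report",
    sprintf("%s: cost %.2f, %.3f QALYs", s$reference$strategy,
            s$reference$total_cost, s$reference$total_qalys),
    sprintf("%s: cost %.2f, %.3f QALYs", s$comparator$strategy,
            s$comparator$total_cost, s$comparator$total_qalys),
    sprintf("Incremental cost %.2f, incremental effect %.4f QALYs",
            s$delta_cost, s$delta_effect),
    sprintf("ICER %.2f per QALY at WTP %.2f: %s", s$icer, s$wtp, s$decision)
  )
  for (extra in c("tornado.csv", "ceac.csv", "cohort_summary.csv")) {
    p <- file.path(out_dir, extra)
    if (file.exists(p)) {
      lines <- c(lines, "", paste0("-- ", extra, " --"),
                 readLines(p, n = 12L))
    }
  }
  p <- file.path(out_dir, "report.txt")
  writeLines(lines, p)
  p
}
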