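#' Load and validate an analysis configuration
#'
#' Reads a YAML or JSON configuration with two strategy blocks (`reference`
#' and `comparator`) and applies the analysis defaults: 120 monthly cycles,
#' willingness-to-pay 268,074 per QALY (three times 2023 Chinese per-capita
#' GDP), 5% annual discount, half-cycle correction on, ±20% sensitivity
#' ranges and 1,000 PSA draws. Each strategy block requires `median_dfs`,
#' `median_os`, `u_dfs`, `u_pd` and `initial_cost`; per-cycle costs come
#' either directly (`cycle_cost_alive`) or via a calibration target
#' (`target_total_cost`, see [calibrate_state_costs()]). Validation errors
#' name the offending field path.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cea_config` object.
#' @seealso [run_cea()], [run_pipeline()]
#' @examples
#' cfg <- load_config(system.file("extdata", "paper_baseline.yaml",
#'                                package = "pdcea"))
#' cfg$wtp
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !is.list(raw) || length(raw) == 0L) {
    stop("configuration file is empty: ", path, call. = FALSE)
  }
  as_cea_config(raw)
}

# build a validated cea_config from a plain list
as_cea_config <- function(raw) {
  bad <- function(field, why) {
    stop("invalid configuration: `", field, "` ", why, call. = FALSE)
  }
  num_field <- function(block, block_name, field, required = TRUE,
                        lower = -Inf, upper = Inf) {
    path <- paste(block_name, field, sep = ".")
    x <- block[[field]]
    if (is.null(x)) {
      if (required) bad(path, "is missing")
      return(NULL)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      bad(path, "must be a single finite number")
    }
    if (x < lower || x > upper) {
      bad(path, sprintf("must lie in [%g, %g]", lower, upper))
    }
    x
  }
  parse_strategy <- function(block_name) {
    block <- raw[[block_name]]
    if (is.null(block) || !is.list(block)) {
      bad(block_name, "strategy block is missing")
    }
    s <- list(
      label = as.character(block$label %||% block_name),
      median_dfs = num_field(block, block_name, "median_dfs", lower = 1e-9),
      median_os = num_field(block, block_name, "median_os", lower = 1e-9),
      u_dfs = num_field(block, block_name, "u_dfs", lower = 0, upper = 1),
      u_pd = num_field(block, block_name, "u_pd", lower = 0, upper = 1),
      initial_cost = num_field(block, block_name, "initial_cost", lower = 0),
      cycle_cost_alive = num_field(block, block_name, "cycle_cost_alive",
                                   required = FALSE, lower = 0),
      target_total_cost = num_field(block, block_name, "target_total_cost",
                                    required = FALSE, lower = 0)
    )
    if (s$median_os <= s$median_dfs) {
      bad(paste0(block_name, ".median_os"), "must exceed median_dfs")
    }
    if (s$u_pd > s$u_dfs) {
      bad(paste0(block_name, ".u_pd"), "must not exceed u_dfs")
    }
    if (!is.null(s$target_total_cost) && s$target_total_cost < s$initial_cost) {
      bad(paste0(block_name, ".target_total_cost"),
          "must be at least initial_cost")
    }
    s
  }
  sens <- raw$sensitivity %||% list()
  cfg <- list(
    reference = parse_strategy("reference"),
    comparator = parse_strategy("comparator"),
    n_cycles = num_field(raw, "", "n_cycles", required = FALSE,
                         lower = 1) %||% 120,
    wtp = num_field(raw, "", "wtp", required = FALSE, lower = 0) %||% 268074,
    discount = num_field(raw, "", "discount", required = FALSE, lower = 0,
                         upper = 1 - 1e-9) %||% 0.05,
    half_cycle = raw$half_cycle %||% TRUE,
    sensitivity = list(
      fraction = num_field(sens, "sensitivity", "fraction", required = FALSE,
                           lower = 0, upper = 1 - 1e-9) %||% 0.20,
      n_draws = num_field(sens, "sensitivity", "n_draws", required = FALSE,
                          lower = 1) %||% 1000,
      seed = as.integer(num_field(sens, "sensitivity", "seed",
                                  required = FALSE) %||% 1),
      distributions = sens$distributions %||% "uniform"
    ),
    cohort = raw$cohort %||% list(),
    reported = raw$reported %||% NULL
  )
  if (!is.logical(cfg$half_cycle) || length(cfg$half_cycle) != 1L) {
    bad("half_cycle", "must be TRUE or FALSE")
  }
  structure(cfg, class = "cea_config")
}

#' Serialise an analysis configuration to YAML
#'
#' Writes a [load_config()] result back to disk; `load_config()` on the
#' written file reproduces the configuration (round-trip identity).
#'
#' @param config A `cea_config`.
#' @param path Output path (`.yaml`).
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  plain <- unclass(config)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  plain$reference <- plain$reference[!vapply(plain$reference, is.null, logical(1))]
  plain$comparator <- plain$comparator[!vapply(plain$comparator, is.null, logical(1))]
  yaml::write_yaml(plain, path)
  invisible(path)
}

# strategy_params from a parsed config block plus shared settings; per-cycle
# cost resolved from the calibration target when not given directly
resolve_strategy <- function(block, discount, n_cycles, half_cycle) {
  mat <- build_transition_matrix(block$median_dfs, block$median_os)
  trace <- run_trace(mat, n_cycles, half_cycle = half_cycle)
  cycle_cost <- block$cycle_cost_alive
  if (is.null(cycle_cost)) {
    cycle_cost <- if (!is.null(block$target_total_cost)) {
      calibrate_state_costs(trace, block$target_total_cost,
                            block$initial_cost, discount)
    } else {
      0
    }
  }
  params <- strategy_params(block$label, block$median_dfs, block$median_os,
                            block$u_dfs, block$u_pd, block$initial_cost,
                            cycle_cost, discount)
  list(params = params, matrix = mat, trace = trace)
}

#' Run the full cost-effectiveness analysis in memory
#'
#' Builds both strategies' transition matrices and traces, resolves per-cycle
#' costs (calibrating to `target_total_cost` where configured), evaluates
#' discounted costs and QALYs, and computes the incremental comparison at the
#' configured willingness-to-pay.
#'
#' @param config A `cea_config` from [load_config()].
#' @return A `cea_result`: per-strategy `params`/`matrix`/`trace`/`econ`,
#'   the `ce` comparison, and the `config`.
#' @export
run_cea <- function(config) {
  stopifnot(inherits(config, "cea_config"))
  ref <- resolve_strategy(config$reference, config$discount, config$n_cycles,
                          config$half_cycle)
  cmp <- resolve_strategy(config$comparator, config$discount, config$n_cycles,
                          config$half_cycle)
  ref$econ <- evaluate_strategy(ref$params, ref$trace)
  cmp$econ <- evaluate_strategy(cmp$params, cmp$trace)
  structure(
    list(reference = ref, comparator = cmp,
         ce = icer(ref$econ, cmp$econ, config$wtp), config = config),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  print(x$reference$econ)
  print(x$comparator$econ)
  print(x$ce)
  invisible(x)
}
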