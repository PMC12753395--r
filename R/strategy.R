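#' Strategy parameter set
#'
#' Bundles one treatment arm's model inputs: median disease-free and overall
#' survival (months), state utilities, the one-time initial (surgical
#' admission) cost accrued at cycle 0, a per-cycle cost while alive, and the
#' annual discount rate.
#'
#' @param label Strategy name, e.g. `"OPD"` or `"LPD"`.
#' @param median_dfs,median_os Median DFS and OS in months,
#'   `0 < median_dfs < median_os`.
#' @param u_dfs,u_pd Utilities of the disease-free and progressed states,
#'   `0 <= u_pd <= u_dfs <= 1`.
#' @param initial_cost One-time cost at cycle 0 (currency), non-negative.
#' @param cycle_cost_alive Cost per cycle while alive (currency),
#'   non-negative; often obtained from [calibrate_state_costs()].
#' @param annual_discount Annual discount rate in `[0, 1)`; default 0.05.
#' @return A `strategy_params` object.
#' @examples
#' strategy_params("OPD", 14, 22, 0.792, 0.650, initial_cost = 95994.18)
#' @export
strategy_params <- function(label, median_dfs, median_os, u_dfs, u_pd,
                            initial_cost, cycle_cost_alive = 0,
                            annual_discount = 0.05) {
  check_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  for (nm in c("median_dfs", "median_os", "u_dfs", "u_pd", "initial_cost",
               "cycle_cost_alive", "annual_discount")) {
    check_num(get(nm), nm)
  }
  if (median_dfs <= 0 || median_os <= median_dfs) {
    stop("medians must satisfy 0 < median_dfs < median_os", call. = FALSE)
  }
  if (u_pd < 0 || u_dfs > 1 || u_pd > u_dfs) {
    stop("utilities must satisfy 0 <= u_pd <= u_dfs <= 1", call. = FALSE)
  }
  if (initial_cost < 0 || cycle_cost_alive < 0) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (annual_discount < 0 || annual_discount >= 1) {
    stop("`annual_discount` must lie in [0, 1)", call. = FALSE)
  }
  new_strategy_params(label = as.character(label), median_dfs = median_dfs,
                      median_os = median_os, u_dfs = u_dfs, u_pd = u_pd,
                      initial_cost = initial_cost,
                      cycle_cost_alive = cycle_cost_alive,
                      annual_discount = annual_discount)
}

# unchecked constructor; sensitivity analysis perturbs fields past the
# ordering constraints (e.g. sampled u_pd may exceed sampled u_dfs)
new_strategy_params <- function(label, median_dfs, median_os, u_dfs, u_pd,
                                initial_cost, cycle_cost_alive,
                                annual_discount) {
  structure(
    list(label = label, median_dfs = median_dfs, median_os = median_os,
         u_dfs = u_dfs, u_pd = u_pd, initial_cost = initial_cost,
         cycle_cost_alive = cycle_cost_alive,
         annual_discount = annual_discount),
    class = "strategy_params"
  )
}

#' @export
print.strategy_params <- function(x, ...) {
  cat("Strategy", x$label, "\n")
  cat(sprintf("  median DFS %g mo, median OS %g mo\n", x$median_dfs, x$median_os))
  cat(sprintf("  utilities: DFS %.3f, PD %.3f\n", x$u_dfs, x$u_pd))
  cat(sprintf("  initial cost %.2f, per-cycle alive cost %.2f, discount %.1f%%/yr\n",
              x$initial_cost, x$cycle_cost_alive, 100 * x$annual_discount))
  invisible(x)
}
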