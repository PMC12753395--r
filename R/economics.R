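#' Per-cycle discount factor from an annual rate
#'
#' Compound annual discounting converted to monthly cycles: the factor for
#' cycle `t` is \eqn{(1 + r)^{-t/12}}, so cycle 12 discounts by exactly one
#' year.
#'
#' @param annual_rate Annual discount rate in `[0, 1)`.
#' @param cycles Integer cycle indices (vectorised).
#' @return Discount factors in (0, 1].
#' @examples
#' monthly_discount_factor(0.05, 12)  # 1/1.05
#' @export
monthly_discount_factor <- function(annual_rate, cycles) {
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L ||
      !is.finite(annual_rate) || annual_rate < 0 || annual_rate >= 1) {
    stop("`annual_rate` must lie in [0, 1)", call. = FALSE)
  }
  (1 + annual_rate)^(-cycles / 12)
}

#' Discounted costs and QALYs of one strategy over a trace
#'
#' Accrues discounted quality-adjusted life years and costs over a cohort
#' trace. Per cycle `t` (discount factor `d(t)`):
#' QALYs accrue as `d(t) * (occ_dfs * u_dfs + occ_pd * u_pd) / 12`
#' (occupancy is in months; utilities are per year), and costs as
#' `d(t) * (occ_dfs + occ_pd) * cycle_cost_alive`. The one-time initial cost
#' enters undiscounted at cycle 0. The death state carries zero utility and
#' zero cost.
#'
#' @param params A [strategy_params()] object.
#' @param trace A [run_trace()] result over the DFS/PD/D states.
#' @return An `econ_result`: list with `total_cost`, `total_qalys`,
#'   per-cycle breakdowns, and the strategy label.
#' @export
evaluate_strategy <- function(params, trace) {
  stopifnot(inherits(params, "strategy_params"))
  if (!inherits(trace, "markov_trace") ||
      !all(c("DFS", "PD") %in% trace$states)) {
    stop("`trace` must be a markov_trace over the DFS/PD/D states",
         call. = FALSE)
  }
  occ <- trace$occupancy
  disc <- monthly_discount_factor(params$annual_discount,
                                  seq_len(trace$n_cycles))
  cycle_qalys <- disc * (occ[, "DFS"] * params$u_dfs +
                           occ[, "PD"] * params$u_pd) / 12
  cycle_costs <- disc * (occ[, "DFS"] + occ[, "PD"]) * params$cycle_cost_alive
  structure(
    list(label = params$label,
         total_cost = params$initial_cost + sum(cycle_costs),
         total_qalys = sum(cycle_qalys),
         cycle_costs = cycle_costs, cycle_qalys = cycle_qalys,
         initial_cost = params$initial_cost,
         annual_discount = params$annual_discount,
         n_cycles = trace$n_cycles),
    class = "econ_result"
  )
}

#' Construct an economic result from reported totals
#'
#' Wraps already-computed cumulative cost and QALY totals (e.g. a published
#' cost-effectiveness table used as a worked example) so they can flow into
#' [icer()] and [nmb()] alongside trace-evaluated results.
#'
#' @param label Strategy name.
#' @param total_cost Discounted cumulative cost (currency).
#' @param total_qalys Discounted cumulative QALYs, non-negative.
#' @return An `econ_result` without per-cycle breakdowns.
#' @export
econ_result <- function(label, total_cost, total_qalys) {
  if (!is.numeric(total_cost) || !is.numeric(total_qalys) ||
      length(total_cost) != 1L || length(total_qalys) != 1L ||
      total_qalys < 0) {
    stop("totals must be single numbers with non-negative QALYs",
         call. = FALSE)
  }
  structure(
    list(label = as.character(label), total_cost = total_cost,
         total_qalys = total_qalys, cycle_costs = NULL, cycle_qalys = NULL,
         initial_cost = NA_real_, annual_discount = NA_real_,
         n_cycles = NA_integer_),
    class = "econ_result"
  )
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("%s: cumulative cost %.2f, effects %.3f QALYs\n",
              x$label, x$total_cost, x$total_qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio and WTP decision
#'
#' Computes the incremental cost and effect of a comparator strategy over a
#' reference, the ICER `delta_cost / delta_effect`, and the decision against
#' a willingness-to-pay threshold: with positive incremental effect and cost
#' the comparator is cost-effective when the ICER does not exceed WTP; a
#' comparator that is at least as cheap and more effective is dominant;
#' costlier and no more effective is dominated. When both increments are
#' negative the ICER is savings per QALY forgone and the comparator is
#' cost-effective when that ratio is at least the WTP (`reversed = TRUE`).
#' A zero incremental effect leaves the ICER undefined (`NA`) and the
#' decision rests on the cost sign alone.
#'
#' @param reference,comparator `econ_result` objects.
#' @param wtp Willingness-to-pay threshold (currency per QALY).
#' @return A `ce_result`: `delta_cost`, `delta_effect`, `icer`, `decision`,
#'   `wtp`, `reversed`, and the two labels.
#' @examples
#' opd <- econ_result("OPD", 269164.88, 2.190)
#' lpd <- econ_result("LPD", 282340.19, 2.254)
#' icer(opd, lpd, wtp = 268074)
#' @export
icer <- function(reference, comparator, wtp) {
  stopifnot(inherits(reference, "econ_result"),
            inherits(comparator, "econ_result"))
  if (!is.numeric(wtp) || length(wtp) != 1L || wtp < 0) {
    stop("`wtp` must be a single non-negative number", call. = FALSE)
  }
  dc <- comparator$total_cost - reference$total_cost
  de <- comparator$total_qalys - reference$total_qalys
  reversed <- FALSE
  if (de == 0) {
    ratio <- NA_real_
    decision <- if (dc < 0) "dominant" else if (dc > 0) "dominated" else "equivalent"
  } else {
    ratio <- dc / de
    if (de > 0 && dc <= 0) {
      decision <- "dominant"
    } else if (de < 0 && dc >= 0) {
      decision <- "dominated"
    } else if (de > 0) {
      decision <- if (ratio <= wtp) "cost-effective" else "not-cost-effective"
    } else {
      reversed <- TRUE
      decision <- if (ratio >= wtp) "cost-effective" else "not-cost-effective"
    }
  }
  structure(
    list(delta_cost = dc, delta_effect = de, icer = ratio,
         decision = decision, wtp = wtp, reversed = reversed,
         reference = reference$label, comparator = comparator$label),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  incremental cost %.2f, incremental effect %.3f QALYs\n",
              x$delta_cost, x$delta_effect))
  if (is.na(x$icer)) {
    cat("  ICER undefined (zero incremental effect)\n")
  } else {
    cat(sprintf("  ICER %.2f per QALY (WTP %.2f)%s\n", x$icer, x$wtp,
                if (x$reversed) " [savings per QALY forgone]" else ""))
  }
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * total_qalys - total_cost`. Strategy A is preferred to B at a given
#' WTP exactly when its NMB is larger; the indifference WTP between two
#' strategies equals their pairwise ICER when the incremental effect is
#' positive.
#'
#' @param result An `econ_result`.
#' @param wtp Willingness-to-pay (currency per QALY), non-negative.
#' @return Net monetary benefit in currency units.
#' @export
nmb <- function(result, wtp) {
  stopifnot(inherits(result, "econ_result"))
  if (!is.numeric(wtp) || any(wtp < 0)) {
    stop("`wtp` must be non-negative", call. = FALSE)
  }
  wtp * result$total_qalys - result$total_cost
}

#' Solve the per-cycle alive cost that reproduces a cumulative cost total
#'
#' The cost accrual of [evaluate_strategy()] is linear in the per-cycle
#' alive cost, so the value reproducing a target discounted cumulative cost
#' has the closed form
#' `(target - initial_cost) / sum(d(t) * (occ_dfs + occ_pd))`.
#' Re-running [evaluate_strategy()] with the returned value reproduces the
#' target exactly (to floating-point precision).
#'
#' @param trace A `markov_trace`.
#' @param target_total_cost Target discounted cumulative cost, at least
#'   `initial_cost`.
#' @param initial_cost One-time cycle-0 cost.
#' @param annual_discount Annual discount rate.
#' @return The per-cycle alive cost (currency per cycle).
#' @export
calibrate_state_costs <- function(trace, target_total_cost, initial_cost,
                                  annual_discount) {
  stopifnot(inherits(trace, "markov_trace"))
  if (!is.numeric(target_total_cost) || target_total_cost < initial_cost) {
    stop("`target_total_cost` must be at least `initial_cost`", call. = FALSE)
  }
  occ <- trace$occupancy
  disc <- monthly_discount_factor(annual_discount, seq_len(trace$n_cycles))
  denom <- sum(disc * (occ[, "DFS"] + occ[, "PD"]))
  if (denom <= 1e-12) {
    stop("trace has no discounted alive person-time to carry per-cycle costs",
         call. = FALSE)
  }
  (target_total_cost - initial_cost) / denom
}
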