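# Parameter registry for sensitivity analyses: every tunable scalar of the
# two-strategy model, its baseline, and the cap applied to its upper bound
# (1 for probabilities/utilities, uncapped for costs). Transition
# probabilities are the full-precision exit probabilities of each strategy's
# matrix; perturbing one re-derives the same-row stay probability as the
# residual, preserving row sums.
param_registry <- function(reference, comparator, include_discount = TRUE) {
  one <- function(params, role) {
    m <- build_transition_matrix(params$median_dfs, params$median_os)
    data.frame(
      name = paste(params$label,
                   c("initial_cost", "cycle_cost_alive", "u_dfs", "u_pd",
                     "p_dfs_pd", "p_dfs_d", "p_pd_d"), sep = "."),
      role = role,
      field = c("initial_cost", "cycle_cost_alive", "u_dfs", "u_pd",
                "p_dfs_pd", "p_dfs_d", "p_pd_d"),
      baseline = c(params$initial_cost, params$cycle_cost_alive,
                   params$u_dfs, params$u_pd,
                   m["DFS", "PD"], m["DFS", "D"], m["PD", "D"]),
      cap = c(Inf, Inf, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
  }
  reg <- rbind(one(reference, "reference"), one(comparator, "comparator"))
  if (include_discount) {
    if (reference$annual_discount != comparator$annual_discount) {
      stop("strategies must share a discount rate", call. = FALSE)
    }
    reg <- rbind(reg, data.frame(
      name = "discount", role = "shared", field = "annual_discount",
      baseline = reference$annual_discount, cap = 1 - 1e-9,
      stringsAsFactors = FALSE
    ))
  }
  reg
}

# Re-evaluate the two-strategy model with named parameter overrides
# (names as in param_registry). Returns NULL when an override leaves the
# DFS row with exit probabilities summing above 1 (an invalid draw).
eval_pair <- function(reference, comparator, wtp, n_cycles = 120,
                      values = NULL, half_cycle = TRUE) {
  run_one <- function(params) {
    m <- build_transition_matrix(params$median_dfs, params$median_os)
    p <- list(p_dfs_pd = m["DFS", "PD"], p_dfs_d = m["DFS", "D"],
              p_pd_d = m["PD", "D"])
    pick <- function(field, default) {
      key <- paste(params$label, field, sep = ".")
      if (!is.null(values) && key %in% names(values)) values[[key]] else default
    }
    p$p_dfs_pd <- pick("p_dfs_pd", p$p_dfs_pd)
    p$p_dfs_d <- pick("p_dfs_d", p$p_dfs_d)
    p$p_pd_d <- pick("p_pd_d", p$p_pd_d)
    if (p$p_dfs_pd + p$p_dfs_d > 1) {
      return(NULL)
    }
    disc <- if (!is.null(values) && "discount" %in% names(values)) {
      values[["discount"]]
    } else {
      params$annual_discount
    }
    pp <- new_strategy_params(
      label = params$label, median_dfs = params$median_dfs,
      median_os = params$median_os,
      u_dfs = pick("u_dfs", params$u_dfs),
      u_pd = pick("u_pd", params$u_pd),
      initial_cost = pick("initial_cost", params$initial_cost),
      cycle_cost_alive = pick("cycle_cost_alive", params$cycle_cost_alive),
      annual_discount = disc
    )
    mat <- transition_matrix(p$p_dfs_pd, p$p_dfs_d, p$p_pd_d)
    evaluate_strategy(pp, run_trace(mat, n_cycles, half_cycle = half_cycle))
  }
  ref <- run_one(reference)
  cmp <- run_one(comparator)
  if (is.null(ref) || is.null(cmp)) {
    return(NULL)
  }
  icer(ref, cmp, wtp)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full two-strategy pipeline with each parameter in turn set to
#' the lower and upper end of its plausible range (baseline ± `fraction`,
#' capped at 1 for probabilities and utilities) while all other parameters
#' stay at baseline, recording the ICER at each end. Varied parameters: both
#' strategies' initial and per-cycle costs, utilities, and transition
#' probabilities (with the same-row stay probability re-derived as the
#' residual), plus the shared discount rate. Entries are sorted by
#' descending span, ready for a tornado diagram.
#'
#' @param reference,comparator [strategy_params()] for the two arms.
#' @param wtp Willingness-to-pay threshold.
#' @param n_cycles Trace horizon; default 120.
#' @param fraction Relative range half-width; default 0.20.
#' @param parameters Optional character vector restricting which registry
#'   parameters to vary (names like `"LPD.initial_cost"`); unknown names are
#'   an error.
#' @param half_cycle Apply the half-cycle correction; default `TRUE`.
#' @return A `tornado_result` data frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, with the baseline ICER as an attribute.
#' @export
one_way_tornado <- function(reference, comparator, wtp, n_cycles = 120,
                            fraction = 0.20, parameters = NULL,
                            half_cycle = TRUE) {
  reg <- param_registry(reference, comparator, include_discount = TRUE)
  if (!is.null(parameters)) {
    unknown <- setdiff(parameters, reg$name)
    if (length(unknown)) {
      stop("unknown sensitivity parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[reg$name %in% parameters, , drop = FALSE]
  }
  base_ce <- eval_pair(reference, comparator, wtp, n_cycles,
                       half_cycle = half_cycle)
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    rng <- param_range(reg$baseline[i], fraction, cap = reg$cap[i])
    at <- function(v) {
      ce <- eval_pair(reference, comparator, wtp, n_cycles,
                      values = setNames(list(v), reg$name[i]),
                      half_cycle = half_cycle)
      if (is.null(ce)) NA_real_ else ce$icer
    }
    icer_low <- at(rng[["lower"]])
    icer_high <- at(rng[["upper"]])
    data.frame(parameter = reg$name[i], low = rng[["lower"]],
               high = rng[["upper"]], icer_low = icer_low,
               icer_high = icer_high, span = abs(icer_high - icer_low),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_icer") <- base_ce$icer
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Samples every model parameter independently from its uncertainty
#' distribution, rebuilds both strategies' transition matrices (stay
#' probabilities re-derived as residuals) and re-runs the model, recording
#' the incremental cost and effect of each draw. The default distributions
#' are uniform on the ± `fraction` ranges (capped at 1 for probabilities and
#' utilities); `"beta-gamma"` uses moment-matched beta distributions for
#' probabilities/utilities and gamma for costs with the same standard
#' deviation as the uniform ranges. Draws whose perturbed DFS row exceeds
#' probability 1 are resampled (at most `max_retries` attempts each).
#'
#' @param reference,comparator [strategy_params()] for the two arms.
#' @param wtp Willingness-to-pay threshold, stored for downstream CEAC use.
#' @param n_cycles Trace horizon; default 120.
#' @param n_draws Number of Monte Carlo draws; default 1000.
#' @param fraction Relative uncertainty half-width; default 0.20.
#' @param seed Integer seed; the analysis is bit-reproducible given the seed.
#' @param distributions `"uniform"` (default) or `"beta-gamma"`.
#' @param parameters Optional character vector restricting which registry
#'   parameters are sampled (others stay at baseline); unknown names are an
#'   error.
#' @param include_discount Sample the discount rate too? Default `FALSE`
#'   (varied in the tornado only).
#' @param half_cycle Apply the half-cycle correction; default `TRUE`.
#' @param max_retries Resampling cap per draw before failing; default 100.
#' @return A `psa_result`: `draws` data frame (`draw`, `delta_cost`,
#'   `delta_effect`), the matrix of sampled parameters, `seed`, `n_draws`,
#'   `wtp`.
#' @export
psa <- function(reference, comparator, wtp, n_cycles = 120, n_draws = 1000,
                fraction = 0.20, seed = 1L,
                distributions = c("uniform", "beta-gamma"),
                parameters = NULL, include_discount = FALSE,
                half_cycle = TRUE, max_retries = 100) {
  distributions <- match.arg(distributions)
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be at least 1", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  reg <- param_registry(reference, comparator,
                        include_discount = include_discount)
  if (!is.null(parameters)) {
    unknown <- setdiff(parameters, reg$name)
    if (length(unknown)) {
      stop("unknown sensitivity parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[reg$name %in% parameters, , drop = FALSE]
  }
  set.seed(seed)
  sample_params <- function() {
    vals <- numeric(nrow(reg))
    for (i in seq_len(nrow(reg))) {
      b <- reg$baseline[i]
      rng <- param_range(b, fraction, cap = reg$cap[i])
      if (distributions == "uniform" || b == 0 || fraction == 0) {
        vals[i] <- runif(1, rng[["lower"]], rng[["upper"]])
      } else if (is.finite(reg$cap[i])) {
        # beta, moment-matched to the uniform range's mean and sd
        s <- (rng[["upper"]] - rng[["lower"]]) / sqrt(12)
        mu <- (rng[["upper"]] + rng[["lower"]]) / 2
        nu <- mu * (1 - mu) / s^2 - 1
        vals[i] <- rbeta(1, mu * nu, (1 - mu) * nu)
      } else {
        s <- (rng[["upper"]] - rng[["lower"]]) / sqrt(12)
        shape <- (b / s)^2
        vals[i] <- rgamma(1, shape = shape, rate = shape / b)
      }
    }
    setNames(as.list(vals), reg$name)
  }
  draws <- data.frame(draw = seq_len(n_draws), delta_cost = NA_real_,
                      delta_effect = NA_real_)
  sampled <- matrix(NA_real_, n_draws, nrow(reg),
                    dimnames = list(NULL, reg$name))
  for (d in seq_len(n_draws)) {
    ce <- NULL
    for (try in seq_len(max_retries)) {
      vals <- sample_params()
      ce <- eval_pair(reference, comparator, wtp, n_cycles, values = vals,
                      half_cycle = half_cycle)
      if (!is.null(ce)) break
    }
    if (is.null(ce)) {
      stop("could not sample a valid parameter set in ", max_retries,
           " attempts (draw ", d, ")", call. = FALSE)
    }
    draws$delta_cost[d] <- ce$delta_cost
    draws$delta_effect[d] <- ce$delta_effect
    sampled[d, ] <- unlist(vals)
  }
  structure(
    list(draws = draws, params = sampled, seed = seed, n_draws = n_draws,
         wtp = wtp, fraction = fraction, distributions = distributions),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws, seed",
      x$seed, "\n")
  cat(sprintf("  mean incremental cost %.2f, mean incremental effect %.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the fraction of PSA draws
#' in which the comparator has positive incremental net monetary benefit
#' (`wtp * delta_effect - delta_cost > 0`), i.e. the probability the
#' comparator is cost-effective at that WTP.
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid Non-negative WTP grid; default 0 to 400,000 in steps of
#'   10,000 (currency per QALY).
#' @return A `ceac_curve` data frame with columns `wtp`, `probability`; every
#'   probability is an exact draw-count fraction.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 400000, by = 10000)) {
  stopifnot(inherits(psa_result, "psa_result"))
  if (length(wtp_grid) == 0L || any(wtp_grid < 0)) {
    stop("`wtp_grid` must be a non-empty, non-negative grid", call. = FALSE)
  }
  if (nrow(psa_result$draws) == 0L) {
    stop("PSA result contains no draws", call. = FALSE)
  }
  dc <- psa_result$draws$delta_cost
  de <- psa_result$draws$delta_effect
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  structure(
    data.frame(wtp = wtp_grid, probability = prob),
    class = c("ceac_curve", "data.frame")
  )
}
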