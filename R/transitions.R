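#' Monthly event probability from a median time-to-event
#'
#' Converts a median time-to-event (in months) into the probability that the
#' event occurs within one monthly cycle, assuming a constant hazard:
#' \deqn{p = 1 - 0.5^{1/m}}
#' where \eqn{m} is the median in months. Equivalently \eqn{p = 1 - e^{-R}}
#' with monthly rate \eqn{R = \ln(2)/m}.
#'
#' @param median_months Median time to event in months; positive.
#' @return Monthly event probability, strictly in (0, 1). Vectorised.
#' @examples
#' monthly_risk(14)  # ~0.048, DFS -> PD at a 14-month median
#' monthly_risk(1)   # 0.5: half the cohort transitions in one cycle
#' @export
monthly_risk <- function(median_months) {
  if (!is.numeric(median_months) || length(median_months) == 0L ||
      any(!is.finite(median_months)) || any(median_months <= 0)) {
    stop("`median_months` must be a positive, finite number of months",
         call. = FALSE)
  }
  1 - 0.5^(1 / median_months)
}

#' Convert between a monthly rate and a per-cycle probability
#'
#' `rate_to_prob()` maps a constant monthly event rate \eqn{R} to the
#' probability of the event within one cycle, \eqn{P = 1 - e^{-R}};
#' `prob_to_rate()` is its inverse, \eqn{R = -\ln(1 - P)}. The two are exact
#' inverses of one another.
#'
#' @param rate Non-negative event rate per cycle.
#' @param prob Probability in [0, 1); a probability of 1 implies an infinite
#'   rate and is an error.
#' @return A probability (forward) or rate (inverse). Vectorised.
#' @export
rate_to_prob <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be non-negative and finite", call. = FALSE)
  }
  1 - exp(-rate)
}

#' @rdname rate_to_prob
#' @export
prob_to_rate <- function(prob) {
  if (!is.numeric(prob) || any(!is.finite(prob)) || any(prob < 0)) {
    stop("`prob` must be in [0, 1)", call. = FALSE)
  }
  if (any(prob >= 1)) {
    stop("a per-cycle probability of 1 corresponds to an infinite rate",
         call. = FALSE)
  }
  -log(1 - prob)
}

#' Construct a three-state transition matrix from exit probabilities
#'
#' Builds the monthly row-stochastic transition matrix over the states
#' DFS (disease-free survival), PD (progressed disease) and D (death).
#' Structural zeros: PD cannot return to DFS and death is absorbing. The
#' stay probabilities are the residuals `1 - sum(exit probabilities)`.
#'
#' @param p_dfs_pd Monthly probability of progression from DFS.
#' @param p_dfs_d Monthly probability of death from DFS.
#' @param p_pd_d Monthly probability of death from PD.
#' @return A 3x3 matrix of class `transition_matrix` with rows summing to 1.
#' @export
transition_matrix <- function(p_dfs_pd, p_dfs_d, p_pd_d) {
  probs <- c(p_dfs_pd = p_dfs_pd, p_dfs_d = p_dfs_d, p_pd_d = p_pd_d)
  if (!is.numeric(probs) || length(probs) != 3L || any(!is.finite(probs))) {
    stop("transition probabilities must be single finite numbers", call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  p_dfs_dfs <- 1 - p_dfs_pd - p_dfs_d
  if (p_dfs_dfs < -1e-12) {
    stop("DFS exit probabilities sum to more than 1", call. = FALSE)
  }
  p_dfs_dfs <- max(p_dfs_dfs, 0)
  m <- rbind(
    c(p_dfs_dfs, p_dfs_pd, p_dfs_d),
    c(0,         1 - p_pd_d, p_pd_d),
    c(0,         0,          1)
  )
  dimnames(m) <- list(from = .states, to = .states)
  structure(m, class = c("transition_matrix", "matrix", "array"))
}

#' Transition matrix from strategy median survival times
#'
#' Derives the monthly transition matrix of one treatment strategy from its
#' median disease-free survival (DFS) and overall survival (OS), both in
#' months. Under the default (as-published) convention:
#' DFS to PD uses the DFS median, DFS to death uses the OS median, and
#' PD to death uses the post-progression median `median_os - median_dfs`,
#' each converted with [monthly_risk()]. The `"competing-risks"` method
#' instead treats the DFS median as governing the all-cause exit hazard from
#' DFS and splits that exit between progression and death in proportion to
#' the underlying monthly rates.
#'
#' @param median_dfs,median_os Medians in months, `0 < median_dfs < median_os`.
#' @param method `"as-published"` (default) or `"competing-risks"`.
#' @return A `transition_matrix` with the medians attached as an attribute.
#' @examples
#' build_transition_matrix(14, 22)  # open-surgery arm of the worked example
#' @export
build_transition_matrix <- function(median_dfs, median_os,
                                    method = c("as-published", "competing-risks")) {
  method <- match.arg(method)
  if (!is.numeric(median_dfs) || !is.numeric(median_os) ||
      length(median_dfs) != 1L || length(median_os) != 1L ||
      !is.finite(median_dfs) || !is.finite(median_os) || median_dfs <= 0) {
    stop("medians must be single positive numbers of months", call. = FALSE)
  }
  if (median_os <= median_dfs) {
    stop("`median_os` must exceed `median_dfs`: the post-progression median ",
         "is their difference and must be positive", call. = FALSE)
  }
  median_pps <- median_os - median_dfs
  if (median_pps < 0.5) {
    warning("post-progression median is below half a cycle; the monthly ",
            "discretisation is coarse (PD->D probability exceeds 0.75)",
            call. = FALSE)
  }
  if (method == "as-published") {
    p_dfs_pd <- monthly_risk(median_dfs)
    p_dfs_d <- monthly_risk(median_os)
  } else {
    h_exit <- log(2) / median_dfs   # all-cause exit from DFS
    h_d <- log(2) / median_os       # death component
    p_exit <- rate_to_prob(h_exit)
    p_dfs_d <- p_exit * h_d / h_exit
    p_dfs_pd <- p_exit - p_dfs_d
  }
  m <- transition_matrix(p_dfs_pd, p_dfs_d, monthly_risk(median_pps))
  attr(m, "medians") <- c(dfs = median_dfs, os = median_os, pps = median_pps)
  attr(m, "method") <- method
  m
}

#' Plausible range for a one-way sensitivity parameter
#'
#' Returns the lower and upper bound used in deterministic and probabilistic
#' sensitivity analysis: baseline minus/plus `fraction` times the baseline,
#' with the upper bound capped (at 1 for probabilities and utilities; pass
#' `cap = Inf` for costs).
#'
#' @param baseline Non-negative baseline value.
#' @param fraction Relative half-width of the range; default 0.20.
#' @param cap Upper bound cap; default 1.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' param_range(0.048)             # (0.0384, 0.0576)
#' param_range(95994.18, cap = Inf)
#' @export
param_range <- function(baseline, fraction = 0.20, cap = 1) {
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline) ||
      baseline < 0) {
    stop("`baseline` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  c(lower = baseline * (1 - fraction), upper = min(baseline * (1 + fraction), cap))
}

#' Report-style transition probability table
#'
#' Summarises a strategy's transition matrix as the conventional published
#' table: baseline probability plus lower/upper sensitivity bounds for each
#' non-structural transition. Exit probabilities are rounded to `digits`
#' decimals first and the stay probabilities reported as complements of the
#' rounded values, so the printed table is internally consistent at the
#' reported precision; bounds are computed from the rounded baselines and
#' capped at 1.
#'
#' @param mat A `transition_matrix`.
#' @param fraction Relative range half-width for the bounds; default 0.20.
#' @param digits Reporting precision; default 3.
#' @return A data frame with columns `transition`, `baseline`, `lower`, `upper`.
#' @export
transition_table <- function(mat, fraction = 0.20, digits = 3) {
  stopifnot(inherits(mat, "transition_matrix"))
  p_dfs_pd <- round(mat["DFS", "PD"], digits)
  p_dfs_d <- round(mat["DFS", "D"], digits)
  p_pd_d <- round(mat["PD", "D"], digits)
  baseline <- c(
    p_dfs_dfs = 1 - p_dfs_pd - p_dfs_d,
    p_dfs_pd = p_dfs_pd,
    p_dfs_d = p_dfs_d,
    p_pd_pd = 1 - p_pd_d,
    p_pd_d = p_pd_d
  )
  rng <- vapply(baseline, param_range, numeric(2), fraction = fraction)
  data.frame(
    transition = names(baseline),
    baseline = round(unname(baseline), digits),
    lower = round(unname(rng["lower", ]), digits),
    upper = round(unname(rng["upper", ]), digits),
    row.names = NULL
  )
}
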