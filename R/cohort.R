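#' Configuration for the synthetic patient-cohort generator
#'
#' Describes the survival and cost structure of the emulated retrospective
#' cohort: per-arm exponential disease-free survival (DFS) and
#' post-progression survival (PPS) medians, log-normal per-patient direct
#' costs, and administrative censoring from uniform accrual over an entry
#' window with a single follow-up cutoff. Defaults emulate a two-arm surgical
#' cohort of 100 patients per arm accrued over 45 months and followed up to
#' month 87.
#'
#' Because overall survival is the sum of the DFS time and an independent
#' exponential post-progression time, its median is not the sum of the two
#' component medians. When `median_pps` is not supplied it is therefore
#' solved per arm (see [pps_median_for_os()]) so that the latent OS median
#' equals the configured `median_os` — the generator emulates the reported
#' DFS/OS medians, with the post-progression median a derived quantity.
#'
#' @param arms Character vector of arm labels.
#' @param n_per_arm Patients per arm, at least 2.
#' @param median_dfs Per-arm median DFS in months (recycled to the arms).
#' @param median_os Per-arm median overall survival in months; must exceed
#'   the arm's `median_dfs`. Ignored when `median_pps` is given.
#' @param median_pps Optional per-arm median post-progression survival in
#'   months; overrides the OS-median calibration when supplied.
#' @param cost_mean Per-arm mean direct cost (currency).
#' @param cost_cv Coefficient of variation of per-patient costs; default 0.3.
#' @param accrual_window Length of the uniform entry period in months.
#' @param followup_cutoff Follow-up cutoff in months after accrual start;
#'   must exceed `accrual_window`.
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @examples
#' cohort_config(n_per_arm = 50, seed = 7)
#' @export
cohort_config <- function(arms = c("OPD", "LPD"), n_per_arm = 100,
                          median_dfs = c(14, 15), median_os = c(22, 24),
                          median_pps = NULL,
                          cost_mean = c(95994.18, 100013.20), cost_cv = 0.3,
                          accrual_window = 45, followup_cutoff = 87,
                          seed = 1L) {
  n_arms <- length(arms)
  if (n_arms < 1L || anyDuplicated(arms)) {
    stop("`arms` must be distinct labels", call. = FALSE)
  }
  median_dfs <- rep_len(median_dfs, n_arms)
  cost_mean <- rep_len(cost_mean, n_arms)
  if (any(median_dfs <= 0) || any(cost_mean <= 0) || cost_cv <= 0) {
    stop("medians, cost means and `cost_cv` must be positive", call. = FALSE)
  }
  if (is.null(median_pps)) {
    median_os <- rep_len(median_os, n_arms)
    if (any(median_os <= median_dfs)) {
      stop("`median_os` must exceed `median_dfs` in every arm", call. = FALSE)
    }
    median_pps <- mapply(pps_median_for_os, median_dfs, median_os)
  } else {
    median_pps <- rep_len(median_pps, n_arms)
    median_os <- rep(NA_real_, n_arms)
  }
  if (any(median_dfs <= 0) || any(median_pps <= 0) || any(cost_mean <= 0) ||
      cost_cv <= 0) {
    stop("medians, cost means and `cost_cv` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop("`n_per_arm` must be at least 2", call. = FALSE)
  }
  if (accrual_window < 0 || followup_cutoff <= accrual_window) {
    stop("`followup_cutoff` must exceed `accrual_window`", call. = FALSE)
  }
  structure(
    list(arms = as.character(arms), n_per_arm = as.integer(n_per_arm),
         median_dfs = median_dfs, median_os = median_os,
         median_pps = median_pps,
         cost_mean = cost_mean, cost_cv = cost_cv,
         accrual_window = accrual_window, followup_cutoff = followup_cutoff,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Post-progression median matching a target overall-survival median
#'
#' For latent DFS time \eqn{X \sim} exponential with median `median_dfs` and
#' independent post-progression time \eqn{Y \sim} exponential with median
#' \eqn{p}, overall survival \eqn{X + Y} follows a hypoexponential
#' distribution whose median exceeds the sum of the component medians'
#' contribution nonlinearly. This solves for the unique \eqn{p} at which the
#' median of \eqn{X + Y} equals `median_os` (the survival function of the
#' sum is strictly increasing in \eqn{p} at every time point).
#'
#' @param median_dfs,median_os Target medians in months,
#'   `0 < median_dfs < median_os`.
#' @return The post-progression exponential median in months.
#' @examples
#' p <- pps_median_for_os(14, 22)
#' # the sum's survival at 22 months is exactly one half
#' @export
pps_median_for_os <- function(median_dfs, median_os) {
  if (median_dfs <= 0 || median_os <= median_dfs) {
    stop("medians must satisfy 0 < median_dfs < median_os", call. = FALSE)
  }
  a <- log(2) / median_dfs
  surv_sum <- function(p) {
    b <- log(2) / p
    if (abs(a - b) < 1e-12 * a) {
      (1 + a * median_os) * exp(-a * median_os)
    } else {
      (b * exp(-a * median_os) - a * exp(-b * median_os)) / (b - a)
    }
  }
  stats::uniroot(function(p) surv_sum(p) - 0.5,
                 lower = 1e-9, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient latent DFS times (exponential at the configured arm
#' median), independent post-progression survival (exponential), overall
#' survival as their sum, and log-normal direct costs. Entry times are
#' uniform over the accrual window; the administrative censoring time is
#' `followup_cutoff - entry`. Observed times are the minimum of latent and
#' censoring times, with event indicators. DFS here is the composite
#' progression-or-death endpoint, so `t_os >= t_dfs` for every record.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `arm`, `t_dfs`, `dfs_event`, `t_os`,
#'   `os_event`, `direct_cost`; deterministic given `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  out <- vector("list", length(config$arms))
  n <- config$n_per_arm
  for (i in seq_along(config$arms)) {
    t_dfs_lat <- rexp(n, rate = log(2) / config$median_dfs[i])
    t_pps <- rexp(n, rate = log(2) / config$median_pps[i])
    t_os_lat <- t_dfs_lat + t_pps
    entry <- runif(n, 0, config$accrual_window)
    censor <- config$followup_cutoff - entry
    sdlog <- sqrt(log1p(config$cost_cv^2))
    meanlog <- log(config$cost_mean[i]) - sdlog^2 / 2
    out[[i]] <- data.frame(
      arm = config$arms[i],
      t_dfs = pmin(t_dfs_lat, censor),
      dfs_event = t_dfs_lat <= censor,
      t_os = pmin(t_os_lat, censor),
      os_event = t_os_lat <= censor,
      direct_cost = rlnorm(n, meanlog, sdlog)
    )
  }
  do.call(rbind, out)
}

#' Kaplan-Meier median survival time
#'
#' The smallest time at which the Kaplan-Meier product-limit estimate of the
#' survival function drops to 0.5 or below. Returns `NA` when the curve never
#' reaches 0.5 (median undefined under heavy censoring).
#'
#' @param times Non-negative event/censoring times.
#' @param event_flags Logical (or 0/1) event indicators, same length.
#' @return The median in the time unit of `times`, or `NA_real_`.
#' @examples
#' km_median(1:5, rep(TRUE, 5))  # 3
#' @export
km_median <- function(times, event_flags) {
  if (length(times) == 0L) {
    stop("`times` must contain at least one record", call. = FALSE)
  }
  if (length(event_flags) != length(times)) {
    stop("`times` and `event_flags` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be non-negative and finite", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(times, as.logical(event_flags)) ~ 1)
  unname(quantile(fit, probs = 0.5)$quantile)
}

#' Per-arm survival and cost summary of a cohort
#'
#' Kaplan-Meier median DFS and OS plus arithmetic mean direct cost per arm —
#' the summary statistics the Markov model consumes as inputs.
#'
#' @param records Cohort data frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return A data frame with one row per arm: `arm`, `n`, `median_dfs`,
#'   `median_os`, `mean_cost`, and `dfs_median_defined`/`os_median_defined`
#'   flags (`FALSE` when the KM curve never reaches 0.5).
#' @export
summarize_cohort <- function(records) {
  required <- c("arm", "t_dfs", "dfs_event", "t_os", "os_event", "direct_cost")
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !all(required %in% names(records))) {
    stop("`records` must be a non-empty cohort data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  arms <- unique(records$arm)
  res <- lapply(arms, function(a) {
    r <- records[records$arm == a, ]
    m_dfs <- km_median(r$t_dfs, r$dfs_event)
    m_os <- km_median(r$t_os, r$os_event)
    data.frame(arm = a, n = nrow(r), median_dfs = m_dfs, median_os = m_os,
               mean_cost = mean(r$direct_cost),
               dfs_median_defined = !is.na(m_dfs),
               os_median_defined = !is.na(m_os))
  })
  do.call(rbind, res)
}

#' Read and write patient records as delimited text
#'
#' CSV with header `arm,t_dfs,dfs_event,t_os,os_event,direct_cost`, times at
#' 4-decimal precision and event flags encoded 0/1.
#'
#' @param records Cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns the path invisibly; `read_cohort()`
#'   returns the cohort data frame with logical event flags.
#' @export
write_cohort <- function(records, path) {
  df <- data.frame(
    arm = records$arm,
    t_dfs = sprintf("%.4f", records$t_dfs),
    dfs_event = as.integer(records$dfs_event),
    t_os = sprintf("%.4f", records$t_os),
    os_event = as.integer(records$os_event),
    direct_cost = sprintf("%.2f", records$direct_cost)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$dfs_event <- as.logical(df$dfs_event)
  df$os_event <- as.logical(df$os_event)
  if (any(df$t_os < df$t_dfs)) {
    stop("invalid cohort file: `t_os` below `t_dfs`", call. = FALSE)
  }
  if (any(df$direct_cost <= 0)) {
    stop("invalid cohort file: non-positive direct costs", call. = FALSE)
  }
  df
}
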