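#' Sensitivity-analysis plots
#'
#' Standard cost-effectiveness graphics built with ggplot2 (a suggested
#' dependency): a tornado diagram of one-way ICER ranges, the
#' cost-effectiveness acceptability curve, and the incremental
#' cost-effectiveness plane of PSA draws with the WTP line.
#'
#' @param tornado A [one_way_tornado()] result.
#' @param curve A [ceac()] result.
#' @param psa_result A [psa()] result.
#' @param wtp Willingness-to-pay for the CE-plane reference line; defaults
#'   to the PSA's stored WTP.
#' @param top Number of tornado bars to show; default 10.
#' @return A ggplot object.
#' @name cea_plots
NULL

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the ggplot2 package is required for plotting", call. = FALSE)
  }
}

#' @rdname cea_plots
#' @export
plot_tornado <- function(tornado, top = 10) {
  need_ggplot2()
  stopifnot(inherits(tornado, "tornado_result"))
  df <- utils::head(as.data.frame(tornado), top)
  df <- df[!is.na(df$span), , drop = FALSE]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$ymin <- pmin(df$icer_low, df$icer_high)
  df$ymax <- pmax(df$icer_low, df$icer_high)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ymin,
                                         ymax = .data$ymax), linewidth = 4) +
    ggplot2::geom_hline(yintercept = attr(tornado, "baseline_icer"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ICER (currency per QALY)",
                  title = "One-way sensitivity analysis")
}

#' @rdname cea_plots
#' @export
plot_ceac <- function(curve) {
  need_ggplot2()
  stopifnot(inherits(curve, "ceac_curve"))
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (currency per QALY)",
                  y = "Probability comparator is cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' @rdname cea_plots
#' @export
plot_ce_plane <- function(psa_result, wtp = NULL) {
  need_ggplot2()
  stopifnot(inherits(psa_result, "psa_result"))
  wtp <- wtp %||% psa_result$wtp
  ggplot2::ggplot(psa_result$draws,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental effect (QALYs)",
                  y = "Incremental cost",
                  title = "Incremental cost-effectiveness plane")
}
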