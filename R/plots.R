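#' Control-chart plot of pre-diagnosis encounter profiles
#'
#' Plots per-category binned encounter counts against months before
#' diagnosis, with the baseline mean, the upper control limit and the
#' detected lookback window overlaid when a lookback table is given.
#'
#' @param profiles output of [build_category_profiles()].
#' @param lookbacks optional output of [build_lookback_table()].
#' @return a ggplot object.
#' @export
plot_category_profile <- function(profiles, lookbacks = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::scale_x_reverse(breaks = seq(0, 26, 6)) +
    ggplot2::labs(x = "30-day bin before diagnosis (0 = most recent)",
                  y = "pooled encounter count") +
    ggplot2::theme_minimal()
  if (!is.null(lookbacks) && nrow(lookbacks) > 0) {
    lb <- dplyr::mutate(lookbacks,
                        lookback_bin = .data$lookback_days / 30 - 0.5)
    p <- p +
      ggplot2::geom_hline(data = lb,
                          ggplot2::aes(yintercept = .data$ucl),
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::geom_vline(data = lb,
                          ggplot2::aes(xintercept = .data$lookback_bin),
                          linetype = "dotted", colour = "steelblue")
  }
  p
}

#' Diagnostic-interval distribution plot
#'
#' Right-skewed interval distributions by income quintile, optionally
#' faceted by symptom status.
#'
#' @param data per-patient tibble with `interval_days` and `quintile`
#'   (and `status` if present).
#' @param log_x log-scale the interval axis (default TRUE; the
#'   distribution is strongly right-skewed).
#' @return a ggplot object.
#' @export
plot_interval_distribution <- function(data, log_x = TRUE) {
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$interval_days,
                                    colour = factor(.data$quintile))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "diagnostic interval (days)",
                  colour = "income quintile\n(1 = lowest)") +
    ggplot2::theme_minimal()
  if ("status" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~status, scales = "free_y")
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Forest plot of a quantile-regression report
#'
#' Quintile effect estimates (days) with bootstrap confidence
#' intervals, faceted by stratum and quantile level.
#'
#' @param object a `dx_quantile_report` from [run_quantile_models()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dx_quantile_report <- function(object, ...) {
  df <- object %>%
    dplyr::filter(grepl("^quintile", .data$term)) %>%
    dplyr::mutate(tau_lab = paste0(100 * .data$tau, "th percentile"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(stratum ~ tau_lab) +
    ggplot2::labs(x = "difference in conditional quantile vs quintile 5 (days)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
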