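#' Plot a PV loop
#'
#' Volume on the x axis, pressure on the y axis, with the Emax point and the
#' ESPVR line from the origin marked.
#'
#' @param object A `pv_loop`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pv_loop
#' @export
autoplot.pv_loop <- function(object, ...) {
  em <- espvr_slope(object)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume_ml,
                                   y = .data$pressure_mmhg)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_abline(slope = em$espvr, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::annotate("point", x = em$emax_volume, y = em$emax_pressure,
                      colour = "firebrick", size = 2) +
    ggplot2::labs(
      x = "LV volume (mL)", y = "LV pressure (mmHg)",
      title = sprintf("PV loop (%s)", attr(object, "source") %||% "unknown"),
      subtitle = sprintf("ESPVR %.2f mmHg/mL at Emax (%.0f mL, %.0f mmHg)",
                         em$espvr, em$emax_volume, em$emax_pressure)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a normalized elastance curve
#'
#' @param object A `pv_elastance`.
#' @param ... Unused.
#' @return A ggplot with the peak and half-downslope landmarks marked.
#' @method autoplot pv_elastance
#' @export
autoplot.pv_elastance <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_norm, y = .data$e_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "downslope_half_frac"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Cycle fraction", y = "Normalized elastance",
                  subtitle = "Dashed: middle of the downslope (alignment landmark)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for one metric of a paired cohort
#'
#' @param pairs A [pair_metrics()] table.
#' @param metric_name Metric column to plot (e.g. `"sw"`).
#' @param denominator Percent-difference denominator; see
#'   [bland_altman_percent()].
#' @return A ggplot of percent difference vs pairwise mean with bias and
#'   limits of agreement.
#' @export
plot_bland_altman <- function(pairs, metric_name, denominator = "mean") {
  a <- pairs[[paste0(metric_name, "_a")]]
  b <- pairs[[paste0(metric_name, "_b")]]
  ba <- bland_altman_percent(a, b, denominator = denominator)
  df <- tibble(mean_ab = (a + b) / 2, diff_pct = 100 * (a - b) / ((a + b) / 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ab, y = .data$diff_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias_pct, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low_pct, ba$loa_high_pct),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = sprintf("Mean of methods (%s)", metric_name),
                  y = "Difference (%)",
                  subtitle = sprintf("Bias %.1f%%, LoA [%.1f, %.1f]%%",
                                     ba$bias_pct, ba$loa_low_pct,
                                     ba$loa_high_pct)) +
    ggplot2::theme_minimal()
}

#' EDP sensitivity plot
#'
#' @param sweep Output of [edp_sensitivity_sweep()].
#' @param metrics Metric columns to show.
#' @return A ggplot of each metric (normalized to its value at the first grid
#'   point) against assumed EDP.
#' @export
plot_edp_sweep <- function(sweep, metrics = c("sw", "ve", "mep_w", "epev")) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, dplyr::all_of(c("edp", metrics))),
    -"edp", names_to = "metric", values_to = "value"
  )
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$metric),
    rel = .data$value / .data$value[1]
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$edp, y = .data$rel,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Assumed EDP (mmHg)",
                  y = "Metric relative to first grid value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
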