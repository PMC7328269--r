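#' Q-Q plot of a p-value set
#'
#' Observed against expected -log10 p under uniformity; points on the
#' diagonal indicate a calibrated null, points above it at the tail indicate
#' inflation.
#'
#' @param p Numeric vector of p-values, a `dmp_result`, or a tibble from
#'   [qq_points()].
#' @param max_points Thin to at most this many points (tail kept intact).
#' @return A ggplot object.
#' @export
plot_qq <- function(p, max_points = 5000L) {
  pts <- if (inherits(p, "dmp_result")) qq_points(p$table$p_value)
  else if (is.data.frame(p)) p
  else qq_points(p)
  if (nrow(pts) > max_points) {
    keep <- unique(round(seq(1, nrow(pts), length.out = max_points)))
    pts <- dplyr::arrange(pts, dplyr::desc(.data$observed))[keep, ]
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dmp_result <- function(object, ...) plot_qq(object, ...)

#' Metric trend across a sweep
#'
#' @param result A `result_table` (or its `glance()` output).
#' @param x Name of the sweep column (`"k_levels"`, `"n_factors"`,
#'   `"n_samples"`, `"platform"`).
#' @param metric Metric to plot: mean of `"mean_p"`, `"lambda"`, `"n_fdr"` or
#'   `"n_bf"` across repetitions.
#' @return A ggplot object, one line per design/variant present.
#' @export
plot_metric_trend <- function(result, x = "n_samples", metric = "n_fdr") {
  agg <- if (inherits(result, "result_table")) glance(result) else result
  ycol <- paste0(metric, "_mean")
  if (!ycol %in% names(agg)) ycol <- metric
  colour <- intersect(c("design", "variant"), names(agg))[1]
  mapping <- if (!is.na(colour)) {
    ggplot2::aes(x = .data[[x]], y = .data[[ycol]],
                 colour = .data[[colour]], group = .data[[colour]])
  } else {
    ggplot2::aes(x = .data[[x]], y = .data[[ycol]], group = 1)
  }
  ggplot2::ggplot(agg, mapping) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = ycol) +
    ggplot2::theme_minimal()
}

#' Heatmap of induced false positives over a sweep grid
#'
#' @param grid A tibble with columns `x`, `y` and a count column, e.g. mean
#'   FDR-significant probes by factor count and sample size.
#' @param x,y,fill Column names.
#' @return A ggplot object.
#' @export
plot_fdr_heatmap <- function(grid, x = "n_factors", y = "n_samples",
                             fill = "n_fdr_mean") {
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data[[x]]),
                                     y = factor(.data[[y]]),
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3") +
    ggplot2::labs(x = x, y = y, fill = fill) +
    ggplot2::theme_minimal()
}

#' Spike-in detection curves
#'
#' @param curve Output of [spike_detection_curve()].
#' @return A ggplot object: detection fraction against the -log10 target p
#'   of the spiked effects, one line per correction variant.
#' @export
plot_detection_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = -log10(.data$target_p),
                                      y = .data$frac_detected,
                                      colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ "target p of spiked effect"),
                  y = "fraction detected (q < 0.05)") +
    ggplot2::theme_minimal()
}
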