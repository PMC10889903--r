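#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-set RDM as a level-by-level tile map
#'
#' @param object A `cross_rdm` from [build_cross_rdm()].
#' @param ... Unused.
#' @return A ggplot: perceived level vs real level, fill = normalized
#'   dissimilarity `R`.
#' @export
autoplot.cross_rdm <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$real_level), y = factor(.data$perceived_level),
    fill = .data$R
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "R") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "real (horizontal) exemplar level",
      y = "perceived (tilted) exemplar level",
      title = paste0("Cross-set RDM at ", object$layer_id)
    )
}

#' Plot a metrics report: per-level accuracy bars
#'
#' @param object A `metrics_report` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot of accuracy by illusion-strength level, with the overall
#'   accuracy as a dashed reference line.
#' @export
autoplot.metrics_report <- function(object, ...) {
  d <- object$per_level_accuracy
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "illusion-strength level", y = "accuracy",
      title = sprintf("Accuracy by level (overall %.3f)", object$accuracy)
    )
}

#' Plot a permutation test: null histogram with observed accuracy
#'
#' @param object A `permutation_result` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot: histogram of null accuracies, solid line at the
#'   observed accuracy, dashed line at the null percentile baseline.
#' @export
autoplot.permutation_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = max(5, min(30, object$n_perms)),
      fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_vline(xintercept = object$actual_accuracy, linewidth = 1) +
    ggplot2::geom_vline(
      xintercept = object$percentile95, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "null (label-shuffled) test accuracy", y = "count",
      title = sprintf(
        "Permutation test: actual %.3f vs null %dth pct %.3f (%s)",
        object$actual_accuracy, round(object$percentile),
        object$percentile95,
        if (object$significant) "significant" else "not significant"
      )
    )
}

#' Plot aggregated illusion strengths across the stimulus grid
#'
#' @param object A per-stimulus strength tibble from
#'   [aggregate_strengths()].
#' @param ... Unused.
#' @return A ggplot: strength vs diamond width, one line per hue, faceted by
#'   positional setting, with the C1/C2 boundary at 0.4 degrees.
#' @export
autoplot.illusion_strengths <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$diamond_width_px, y = .data$strength_deg,
    colour = .data$color_name, group = .data$color_name
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.4, linetype = "dashed") +
    ggplot2::facet_wrap(~setting, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "diamond width (px)", y = "illusion strength (deg)",
      colour = "hue",
      title = "Aggregated illusion strength by hue and diamond width"
    )
}

#' Display a rendered grating (or heatmap overlay) in a graphics device
#'
#' @param x A `grating_image`.
#' @param y Unused.
#' @param ... Passed to [graphics::rasterImage()].
#' @return Invisibly `x`.
#' @export
plot.grating_image <- function(x, y, ...) {
  d <- dim(x)
  rast <- grDevices::as.raster(unclass(x) / 255)
  graphics::plot.new()
  graphics::plot.window(
    xlim = c(0, d[2]), ylim = c(0, d[1]), asp = 1
  )
  graphics::rasterImage(rast, 0, 0, d[2], d[1], ...)
  invisible(x)
}
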