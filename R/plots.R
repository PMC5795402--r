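#' Plot a breast point cloud projection
#'
#' 2D scatter of a cloud on a chosen coordinate plane, optionally colored
#' by displacement magnitude against a second, corresponding cloud.
#'
#' @param pcl A [breast_pcl()].
#' @param reference Optional corresponding cloud; when given, points are
#'   colored by their per-index displacement magnitude (mm).
#' @param plane Projection plane: `"xz"` (frontal, default), `"xy"`
#'   (axial) or `"yz"` (sagittal).
#' @param surface_only Plot skin points only (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_pcl <- function(pcl, reference = NULL, plane = c("xz", "xy", "yz"),
                     surface_only = TRUE) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- tibble::as_tibble(pcl)
  if (!is.null(reference)) {
    df$displacement <- sqrt((pcl$x - reference$x)^2 +
                              (pcl$y - reference$y)^2 +
                              (pcl$z - reference$z)^2)
  }
  if (surface_only) df <- df[df$is_surface, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]))
  if (is.null(reference)) {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  } else {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$displacement),
                          size = 0.8) +
      ggplot2::scale_colour_viridis_c(name = "displacement (mm)")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (mm)"), y = paste0(ax[2], " (mm)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Bar chart of the mean distance per metric, with the baseline (if
#' present) shown alongside.
#'
#' @param object An `eval_report` from [evaluate_prediction()] /
#'   [evaluate_cases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$what <- ifelse(df$baseline, "baseline (pred = pre)", "prediction")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$mu,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mu - .data$sigma, 0),
                   ymax = .data$mu + .data$sigma),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(y = "distance (mm)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Pair-wise mean distance per model and objective from a
#' [run_experiment()] comparison table.
#'
#' @param object A `bcs_comparison` tibble.
#' @param metric Which metric row to plot (default `"p2p"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcs_comparison <- function(object, metric = "p2p", ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$model, .data$mu),
                                   .data$mu, fill = .data$objective)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("%s mean distance (mm)", metric),
                  fill = "objective") +
    ggplot2::theme_minimal()
}

#' Plot grouped feature importances
#'
#' @param model A `deform_model` of the RF or GBR family.
#' @return A ggplot object (group importance per axis).
#' @export
plot_importances <- function(model) {
  gi <- grouped_importances(model)
  ggplot2::ggplot(gi, ggplot2::aes(stats::reorder(.data$group,
                                                  .data$importance_pct),
                                   .data$importance_pct,
                                   fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance (%)", fill = "axis model") +
    ggplot2::theme_minimal()
}
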