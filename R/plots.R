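# ggplot2 figures: measurement overlay, Bland-Altman, correlation scatter,
# perturbation-sensitivity summary.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overlay plot of a callosal-angle measurement
#'
#' Renders the slice with the ventricle contours, the maximum-margin
#' separating line, the medial-wall ray hits, the base points and the two
#' fitted wall lines.
#'
#' @param object a `ca_result`.
#' @param ... unused.
#' @return A ggplot object (y axis reversed so superior is up).
#' @export
autoplot.ca_result <- function(object, ...) {
  sl <- object$slice$data
  img <- tibble::tibble(
    x = rep(seq_len(ncol(sl)) - 1, each = nrow(sl)),
    y = rep(seq_len(nrow(sl)) - 1, times = ncol(sl)),
    value = as.vector(sl)
  )
  cont <- dplyr::bind_rows(
    tibble::tibble(x = object$contours$left$points[, 1],
                   y = object$contours$left$points[, 2], side = "left"),
    tibble::tibble(x = object$contours$right$points[, 1],
                   y = object$contours$right$points[, 2], side = "right")
  )
  hits <- dplyr::bind_rows(
    tibble::tibble(x = object$medial_walls$left$points[, 1],
                   y = object$medial_walls$left$points[, 2], side = "left"),
    tibble::tibble(x = object$medial_walls$right$points[, 1],
                   y = object$medial_walls$right$points[, 2], side = "right")
  )
  seg <- function(p, d, len = 120) {
    tibble::tibble(x = p[1] - len / 2 * d[1], y = p[2] - len / 2 * d[2],
                   xend = p[1] + len / 2 * d[1], yend = p[2] + len / 2 * d[2])
  }
  wall_segs <- dplyr::bind_rows(
    seg(object$left_wall$base_point, object$left_wall$direction),
    seg(object$right_wall$base_point, object$right_wall$direction)
  )
  sep_seg <- seg(object$separating_line$point,
                 object$separating_line$direction, len = 160)
  bases <- tibble::tibble(
    x = c(object$base_points$left[1], object$base_points$right[1]),
    y = c(object$base_points$left[2], object$base_points$right[2])
  )
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img,
                         ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = cont,
                       ggplot2::aes(.data$x, .data$y, colour = .data$side),
                       linewidth = 0.4) +
    ggplot2::geom_point(data = hits,
                        ggplot2::aes(.data$x, .data$y, colour = .data$side),
                        size = 0.4) +
    ggplot2::geom_segment(
      data = sep_seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "yellow", linetype = 2, linewidth = 0.4) +
    ggplot2::geom_segment(
      data = wall_segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "red", linewidth = 0.6) +
    ggplot2::geom_point(data = bases, ggplot2::aes(.data$x, .data$y),
                        colour = "cyan", shape = 4, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Callosal angle %.1f%s (%s)", object$angle_deg,
                      "°", object$classification),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @return A ggplot object with the bias and 95% limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "Mean of methods", y = "Difference (pred - ref)") +
    ggplot2::theme_minimal()
}

#' Correlation scatter of predicted vs reference angles
#'
#' @param pred,truth numeric vectors (degrees).
#' @param threshold classification threshold highlighted in red (points
#'   whose predicted and reference labels disagree).
#' @return A ggplot object.
#' @export
plot_correlation <- function(pred, truth, threshold = 90) {
  df <- tibble::tibble(
    pred = pred, truth = truth,
    misclassified = (pred < threshold) != (truth < threshold)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$pred,
                                   colour = .data$misclassified)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Reference angle (deg)", y = "Predicted angle (deg)") +
    ggplot2::theme_minimal()
}

#' Perturbation-sensitivity summary plot
#'
#' Mean absolute CA error against perturbation offset, one panel per axis
#' (PC shift, sagittal rotation, axial rotation).
#'
#' @param summary_tbl tibble from [summarize_sensitivity()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(.data$offset, .data$mean_abs_err)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_abs_err - .data$sd_abs_err),
                   ymax = .data$mean_abs_err + .data$sd_abs_err),
      width = 0.3) +
    ggplot2::facet_wrap(~ .data$axis, scales = "free_x") +
    ggplot2::labs(x = "Perturbation offset (voxels / degrees)",
                  y = "Absolute CA error (deg)") +
    ggplot2::theme_minimal()
}
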