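# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a callosal-angle result
#'
#' One row per geometric component (wall lines, separating line, base
#' points) with its key quantities.
#'
#' @param x a `ca_result` from [measure_ca()].
#' @param ... unused.
#' @return A tibble with columns `component`, `x`, `y`, `direction_x`,
#'   `direction_y`, `angle_from_vertical_deg`, `n_points`.
#' @export
tidy.ca_result <- function(x, ...) {
  obj <- x
  tibble::tibble(
    component = c("left_wall", "right_wall", "separating_line",
                  "base_left", "base_right"),
    x = c(obj$left_wall$base_point[1], obj$right_wall$base_point[1],
          obj$separating_line$point[1], obj$base_points$left[1],
          obj$base_points$right[1]),
    y = c(obj$left_wall$base_point[2], obj$right_wall$base_point[2],
          obj$separating_line$point[2], obj$base_points$left[2],
          obj$base_points$right[2]),
    direction_x = c(obj$left_wall$direction[1], obj$right_wall$direction[1],
                    obj$separating_line$direction[1], NA, NA),
    direction_y = c(obj$left_wall$direction[2], obj$right_wall$direction[2],
                    obj$separating_line$direction[2], NA, NA),
    angle_from_vertical_deg = c(obj$left_wall$angle_from_vertical_deg,
                                obj$right_wall$angle_from_vertical_deg,
                                NA, NA, NA),
    n_points = c(obj$left_wall$inlier_count, obj$right_wall$inlier_count,
                 NA, NA, NA)
  )
}

#' Glance at a callosal-angle result
#'
#' @param x a `ca_result`.
#' @param ... unused.
#' @return A one-row tibble: `angle_deg`, `classification`, `margin_px`,
#'   `left_inliers`, `right_inliers`, `n_warnings`.
#' @export
glance.ca_result <- function(x, ...) {
  tibble::tibble(
    angle_deg = x$angle_deg,
    classification = x$classification,
    margin_px = x$separating_line$margin,
    left_inliers = x$left_wall$inlier_count,
    right_inliers = x$right_wall$inlier_count,
    n_warnings = length(x$diagnostics)
  )
}

#' Tidy an agreement report
#'
#' @param x a `ca_agreement` from [agreement_report()].
#' @param ... unused.
#' @return A tibble of statistic/value pairs.
#' @export
tidy.ca_agreement <- function(x, ...) {
  tibble::tibble(
    statistic = c("mae", "mae_sd", "bias", "loa_low", "loa_high",
                  "pearson_r", "pearson_p", "misclassified"),
    value = c(x$mae, x$mae_sd, x$bias, x$loa_low, x$loa_high,
              x$pearson_r, x$pearson_p, x$misclassified)
  )
}

#' Glance at an agreement report
#'
#' @param x a `ca_agreement`.
#' @param ... unused.
#' @return A one-row tibble with every summary statistic.
#' @export
glance.ca_agreement <- function(x, ...) {
  tibble::tibble(
    n = x$n, mae = x$mae, mae_sd = x$mae_sd, bias = x$bias,
    loa_low = x$loa_low, loa_high = x$loa_high,
    pearson_r = x$pearson_r, pearson_p = x$pearson_p,
    misclassified = x$misclassified
  )
}
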