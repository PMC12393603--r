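# Method-agreement statistics: MAE with SD, Bland-Altman bias and 95%
# limits of agreement, Pearson correlation, and the 90-degree
# narrow/wide classification summary. The difference direction is
# predicted - reference throughout.

#' Mean absolute error
#'
#' @param pred,truth numeric vectors of equal length.
#' @return A list with `mae` and `sd` (sample SD, ddof 1, of the absolute
#'   errors; 0 for a single observation).
#' @export
mean_absolute_error <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  ae <- abs(pred - truth)
  list(mae = mean(ae), sd = if (length(ae) > 1L) stats::sd(ae) else 0)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `pred - truth`; the bias is their mean and the 95%
#' limits of agreement are `bias +/- 1.96 * sd(diff)` (sample SD, the
#' standard Bland-Altman form).
#'
#' @param pred,truth numeric vectors of equal length >= 2.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, and `data` (tibble with per-case `mean` and `diff` for
#'   plotting).
#' @export
bland_altman <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- pred - truth
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s,
         data = tibble::tibble(mean = (pred + truth) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> bias ", sprintf("%.3f", x$bias),
      ", 95% limits of agreement [", sprintf("%.3f", x$loa_low), ", ",
      sprintf("%.3f", x$loa_high), "], n = ", nrow(x$data), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r; the p-value comes from the t transform with n - 2
#' degrees of freedom (as in [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps^0.5 ||
      stats::sd(y) < .Machine$double.eps^0.5) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Classify callosal angles as narrow or wide
#'
#' An angle is "narrow" iff it is strictly below the threshold (an angle
#' exactly at the threshold is "wide"). With reference angles, the
#' confusion counts against the reference classification are included.
#'
#' @param angles numeric vector of measured angles (degrees).
#' @param threshold classification threshold (default 90).
#' @param reference optional numeric vector of reference angles.
#' @return A tibble with `angle` and `label`; when `reference` is given,
#'   also `ref_label` and `misclassified`, plus a `confusion` attribute
#'   (2 x 2 table) and a `n_misclassified` attribute.
#' @export
classify_ca <- function(angles, threshold = 90, reference = NULL) {
  stopifnot(all(is.finite(angles)))
  lab <- function(a) factor(ifelse(a < threshold, "narrow", "wide"),
                            levels = c("narrow", "wide"))
  out <- tibble::tibble(angle = angles, label = lab(angles))
  if (!is.null(reference)) {
    stopifnot(length(reference) == length(angles))
    out$ref_label <- lab(reference)
    out$misclassified <- out$label != out$ref_label
    attr(out, "confusion") <- table(predicted = out$label,
                                    reference = out$ref_label)
    attr(out, "n_misclassified") <- sum(out$misclassified)
  }
  out
}

#' Full method-agreement report
#'
#' Combines MAE, Bland-Altman, Pearson correlation and the threshold
#' classification summary for paired predicted/reference measurements.
#'
#' @param pred,truth numeric vectors of equal length >= 3 (predicted and
#'   reference angles, degrees).
#' @param threshold classification threshold (default 90).
#' @return An object of class `ca_agreement` with fields `mae`, `mae_sd`,
#'   `bias`, `loa_low`, `loa_high`, `pearson_r`, `pearson_p`, `n`,
#'   `misclassified`, plus the underlying `bland_altman` object and the
#'   classification tibble.
#' @export
agreement_report <- function(pred, truth, threshold = 90) {
  mae <- mean_absolute_error(pred, truth)
  ba <- bland_altman(pred, truth)
  pr <- pearson_r(pred, truth)
  cls <- classify_ca(pred, threshold = threshold, reference = truth)
  structure(
    list(mae = mae$mae, mae_sd = mae$sd,
         bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
         pearson_r = pr$r, pearson_p = pr$p,
         n = length(pred),
         misclassified = attr(cls, "n_misclassified"),
         threshold = threshold,
         bland_altman = ba, classification = cls),
    class = "ca_agreement"
  )
}

#' @export
print.ca_agreement <- function(x, ...) {
  cat("<ca_agreement> n = ", x$n, " (differences are predicted - reference)",
      "\n  MAE ", sprintf("%.3f", x$mae), " (SD ", sprintf("%.3f", x$mae_sd),
      ")\n  Bland-Altman bias ", sprintf("%.3f", x$bias), ", 95% LoA [",
      sprintf("%.3f", x$loa_low), ", ", sprintf("%.3f", x$loa_high),
      "]\n  Pearson r ", sprintf("%.4f", x$pearson_r), " (p ",
      format.pval(x$pearson_p, digits = 3), ")\n  misclassified at ",
      x$threshold, " deg: ", x$misclassified, "\n", sep = "")
  invisible(x)
}
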