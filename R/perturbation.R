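# Sensitivity experiment: perturb the PC position along the AC-PC axis and
# the plane orientation about the sagittal and axial axes on a grid,
# re-extract the plane, re-segment, re-measure the CA, and compare each
# perturbed measurement to the unperturbed baseline with paired t-tests.

#' Define a perturbation grid
#'
#' One axis is perturbed at a time; every grid contains the zero offset as
#' the baseline anchor. Offsets are cube voxels for PC shifts (1 cube voxel
#' equals `scale_factor` mm, 1 mm for isotropic 1 mm input) and degrees for
#' the rotations.
#'
#' @param pc_shifts,sagittal_degs,axial_degs signed offset vectors; each
#'   must contain 0. Defaults are integer steps -10..10.
#' @return A list of class `perturbation_grid`.
#' @export
perturbation_grid <- function(pc_shifts = -10:10,
                              sagittal_degs = -10:10,
                              axial_degs = -10:10) {
  g <- list(pc_shift = sort(unique(c(0, pc_shifts))),
            sagittal = sort(unique(c(0, sagittal_degs))),
            axial = sort(unique(c(0, axial_degs))))
  structure(g, class = "perturbation_grid")
}

#' Run the perturbation experiment on one case
#'
#' Measures the baseline CA, then for every axis and offset of the grid
#' perturbs the plane ([perturb_plane()]), re-extracts the slice,
#' re-invokes the segmenter and re-measures the CA. Per-offset failures are
#' recorded as `NA`, not raised.
#'
#' @param pre a `preprocessed_volume`.
#' @param landmarks a [landmark_set()] in cube coordinates.
#' @param segmenter a segmenter function (see [file_segmenter()]).
#' @param grid a [perturbation_grid()].
#' @param config a [ca_config()].
#' @param case case identifier recorded in the output (default 1).
#' @return A tibble with columns `case`, `axis` (`"pc_shift"`,
#'   `"sagittal"`, `"axial"`), `offset`, `ca_deg`, `abs_err_deg` (absolute
#'   deviation from the case baseline; exactly 0 at offset 0).
#' @export
run_perturbation_grid <- function(pre, landmarks, segmenter,
                                  grid = perturbation_grid(),
                                  config = ca_config(), case = 1L) {
  stopifnot(inherits(grid, "perturbation_grid"))
  plane0 <- build_plane(landmarks, size = config$slice_size,
                        spacing = config$slice_spacing)
  measure_at <- function(plane) {
    slice <- extract_slice(pre, plane, mode = "intensity")
    mask <- segmenter(slice, pre)
    measure_ca(slice, mask, config)$angle_deg
  }
  baseline <- measure_at(plane0)
  rows <- purrr::map_dfr(names(grid), function(axis) {
    purrr::map_dfr(grid[[axis]], function(off) {
      ca <- if (off == 0) {
        baseline
      } else {
        args <- list(pc_shift = 0, sagittal_deg = 0, axial_deg = 0)
        args[[switch(axis, pc_shift = "pc_shift", sagittal = "sagittal_deg",
                     axial = "axial_deg")]] <- off
        tryCatch(
          measure_at(do.call(perturb_plane, c(list(plane0), args))),
          error = function(e) NA_real_
        )
      }
      tibble::tibble(case = case, axis = axis, offset = off, ca_deg = ca,
                     abs_err_deg = abs(ca - baseline))
    })
  })
  rows
}

#' Paired t-test on matched measurement lists
#'
#' Classic paired t statistic on the differences `perturbed - baseline`
#' with a two-sided p-value.
#'
#' @param baseline,perturbed numeric vectors of equal length >= 3.
#' @return A list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(baseline, perturbed) {
  stopifnot(length(baseline) == length(perturbed))
  n <- length(baseline)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- perturbed - baseline
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (all(abs(d) < .Machine$double.eps^0.5)) {
      return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0))
    }
    stop("zero-variance differences: paired t-test undefined", call. = FALSE)
  }
  ht <- stats::t.test(perturbed, baseline, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Summarize a sensitivity table
#'
#' Aggregates a (multi-case) table from [run_perturbation_grid()] into mean
#' and standard deviation of the absolute CA error per (axis, offset), with
#' a paired t-test of the perturbed angles against the per-case baseline at
#' every nonzero offset.
#'
#' @param tbl tibble from [run_perturbation_grid()] (rows from several
#'   cases may be concatenated).
#' @return A tibble with columns `axis`, `offset`, `n`, `mean_abs_err`,
#'   `sd_abs_err`, `t`, `p`.
#' @export
summarize_sensitivity <- function(tbl) {
  base <- dplyr::filter(tbl, .data$offset == 0, .data$axis == "pc_shift")
  base <- stats::setNames(base$ca_deg, base$case)
  tbl |>
    dplyr::group_by(.data$axis, .data$offset) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$ca_deg)
      out <- tibble::tibble(
        n = sum(ok),
        mean_abs_err = mean(df$abs_err_deg[ok]),
        sd_abs_err = stats::sd(df$abs_err_deg[ok]),
        t = NA_real_, p = NA_real_
      )
      if (key$offset != 0 && sum(ok) >= 3) {
        tt <- tryCatch(
          paired_t_test(base[as.character(df$case[ok])], df$ca_deg[ok]),
          error = function(e) NULL
        )
        if (!is.null(tt)) {
          out$t <- tt$t
          out$p <- tt$p
        }
      }
      out
    }) |>
    dplyr::ungroup()
}
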