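# 3D grid samplers. Points are 0-based fractional voxel indices addressing
# voxel centers; anything outside the grid returns `background`.

#' Trilinear sampling of a 3D array
#'
#' @param arr 3D numeric array.
#' @param pts n x 3 matrix of 0-based fractional voxel coordinates.
#' @param background value for samples outside the grid.
#' @return Numeric vector of length n.
#' @keywords internal
trilinear_sample <- function(arr, pts, background = 0) {
  d <- dim(arr)
  n <- nrow(pts)
  out <- rep(background, n)
  eps <- 1e-9
  inside <- pts[, 1] > -eps & pts[, 1] < d[1] - 1 + eps &
    pts[, 2] > -eps & pts[, 2] < d[2] - 1 + eps &
    pts[, 3] > -eps & pts[, 3] < d[3] - 1 + eps
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  p[, 1] <- clamp(p[, 1], 0, d[1] - 1)
  p[, 2] <- clamp(p[, 2], 0, d[2] - 1)
  p[, 3] <- clamp(p[, 3], 0, d[3] - 1)
  i0 <- pmin(floor(p[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(p[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(p[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  g <- function(di, dj, dk) arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  val <-
    g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    g(1, 1, 0) * fx       * fy       * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 0, 1) * fx       * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy       * fz +
    g(1, 1, 1) * fx       * fy       * fz
  out[inside] <- val
  out
}

#' Nearest-neighbour sampling of a 3D array
#'
#' @inheritParams trilinear_sample
#' @return Numeric vector of length n.
#' @keywords internal
nearest_sample <- function(arr, pts, background = 0) {
  d <- dim(arr)
  idx <- round(pts)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(background, nrow(pts))
  if (any(inside)) {
    out[inside] <- arr[cbind(idx[inside, 1] + 1, idx[inside, 2] + 1,
                             idx[inside, 3] + 1)]
  }
  out
}
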