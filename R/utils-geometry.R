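# Small geometry helpers shared across modules. All 2D points are (x, y)
# with x increasing toward the subject's right and y increasing inferiorly
# (image row convention); 3D coordinates are cube-voxel RAS unless stated.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) {
    stop("cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

#' Rotate 3D vectors about an axis (Rodrigues formula)
#'
#' @param v numeric 3-vector or n x 3 matrix of row vectors.
#' @param axis rotation axis (3-vector, need not be unit length).
#' @param degrees rotation angle in degrees (right-handed about `axis`).
#' @return Rotated vector(s), same shape as `v`.
#' @keywords internal
rotate3 <- function(v, axis, degrees) {
  k <- unit(axis)
  th <- degrees * pi / 180
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  kx <- cbind(
    k[2] * m[, 3] - k[3] * m[, 2],
    k[3] * m[, 1] - k[1] * m[, 3],
    k[1] * m[, 2] - k[2] * m[, 1]
  )
  kdot <- drop(m %*% k)
  out <- m * cos(th) + kx * sin(th) + outer(kdot, k) * (1 - cos(th))
  if (is.matrix(v)) out else drop(out)
}

# Distance from points (n x 2) to the segment a--b; vectorized over points.
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Closest point on segment a--b to point p, with the achieved distance.
closest_point_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else sum((p - a) * ab) / len2
  t <- min(1, max(0, t))
  q <- a + t * ab
  list(point = q, distance = vnorm(p - q))
}

# Pairwise Euclidean distances between two n x 2 / m x 2 point sets.
cross_distances <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# `poly` is an n x 2 matrix of vertices (closed implicitly).
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- logical(nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Signed polygon area by the shoelace formula (positive if counter-clockwise
# in the y-down image convention's own handedness).
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

stage_error <- function(stage, message) {
  stop(structure(
    class = c("caliper_stage_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, message), call = NULL,
         stage = stage)
  ))
}

# Re-raise any error from `expr` with the pipeline stage name attached.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "caliper_stage_error")) stop(e)
    stage_error(stage, conditionMessage(e))
  })
}
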