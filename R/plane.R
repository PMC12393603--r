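# Oblique coronal plane perpendicular to the AC-PC line at the PC:
# construction, slice extraction, perturbation transforms, slice export.
#
# Plane frame convention: normal = unit(AC - PC) (points anterior at
# baseline); u_axis = subject left-to-right axis projected into the plane;
# v_axis = u x normal (points superior). Slice pixel (row i, col j), both
# 0-based, samples the 3D point
#   origin + (j - cx) * spacing * u - (i - cy) * spacing * v
# with (cx, cy) = floor(size/2), so rows increase inferiorly and columns
# increase toward the subject's right.

#' Build the coronal measurement plane
#'
#' Constructs the plane perpendicular to the AC-PC line at the level of the
#' PC, with an in-plane frame chosen so that "up" in the slice is superior
#' and "right" in the slice is the subject's right.
#'
#' @param lm a [landmark_set()] (cube coordinates are used).
#' @param size slice size in pixels, `c(width, height)` (default 224 x 224,
#'   the input size of the downstream ventricle segmenter).
#' @param spacing pixel pitch in cube voxels (default 1).
#' @return An object of class `plane_spec` with fields `origin`, `normal`,
#'   `u_axis`, `v_axis`, `size`, `spacing`.
#' @export
build_plane <- function(lm, size = c(224L, 224L), spacing = 1) {
  stopifnot(inherits(lm, "landmark_set"))
  normal <- unit(lm$ac - lm$pc)
  lr <- c(1, 0, 0)  # subject left-to-right in the RAS cube
  u <- lr - sum(lr * normal) * normal
  if (vnorm(u) < sin(pi / 4) * 0.1) {
    stop("AC-PC line is (nearly) parallel to the left-right axis; ",
         "in-plane roll is undefined", call. = FALSE)
  }
  u <- unit(u)
  v <- unit(pracma_cross(u, normal))
  plane_spec(origin = lm$pc, normal = normal, u_axis = u, v_axis = v,
             size = size, spacing = spacing)
}

# plain cross product (named to avoid masking base::crossprod semantics)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname build_plane
#' @param origin,normal,u_axis,v_axis plane frame (cube voxel coordinates).
#' @export
plane_spec <- function(origin, normal, u_axis, v_axis,
                       size = c(224L, 224L), spacing = 1) {
  size <- as.integer(rep(size, length.out = 2))
  if (any(size <= 0L) || spacing <= 0) {
    stop("plane size and spacing must be positive", call. = FALSE)
  }
  structure(
    list(origin = as.numeric(origin), normal = unit(normal),
         u_axis = unit(u_axis), v_axis = unit(v_axis),
         size = size, spacing = spacing),
    class = "plane_spec"
  )
}

#' @export
print.plane_spec <- function(x, ...) {
  cat("<plane_spec> origin (", paste(signif(x$origin, 5), collapse = ", "),
      "), normal (", paste(signif(x$normal, 4), collapse = ", "),
      "), ", x$size[1], "x", x$size[2], " @ ", x$spacing, " voxel/px\n",
      sep = "")
  invisible(x)
}

#' 3D sample positions of every slice pixel
#'
#' @param plane a `plane_spec`.
#' @return (width*height) x 3 matrix of cube coordinates, pixel-major in
#'   column-then-row order matching `as.vector` of the slice matrix
#'   (rows = height = v direction).
#' @keywords internal
plane_pixel_points <- function(plane) {
  w <- plane$size[1]; h <- plane$size[2]
  cx <- w %/% 2L; cy <- h %/% 2L
  j <- rep(seq_len(w) - 1L, each = h)   # column index, x
  i <- rep(seq_len(h) - 1L, times = w)  # row index, y (inferior)
  du <- (j - cx) * plane$spacing
  dv <- (cy - i) * plane$spacing
  cbind(
    plane$origin[1] + du * plane$u_axis[1] + dv * plane$v_axis[1],
    plane$origin[2] + du * plane$u_axis[2] + dv * plane$v_axis[2],
    plane$origin[3] + du * plane$u_axis[3] + dv * plane$v_axis[3]
  )
}

# 2D slice pixel coords (x = col, y = row) -> 3D cube coords
slice_to_cube <- function(plane, pts2d) {
  m <- if (is.matrix(pts2d)) pts2d else matrix(pts2d, nrow = 1)
  cx <- plane$size[1] %/% 2L; cy <- plane$size[2] %/% 2L
  du <- (m[, 1] - cx) * plane$spacing
  dv <- (cy - m[, 2]) * plane$spacing
  out <- cbind(
    plane$origin[1] + du * plane$u_axis[1] + dv * plane$v_axis[1],
    plane$origin[2] + du * plane$u_axis[2] + dv * plane$v_axis[2],
    plane$origin[3] + du * plane$u_axis[3] + dv * plane$v_axis[3]
  )
  if (is.matrix(pts2d)) out else drop(out)
}

#' Extract a 2D slice along a plane
#'
#' Samples the preprocessed cube (or any 3D array on the cube grid, e.g. a
#' label volume) on the plane's pixel grid: trilinear interpolation for
#' intensities, nearest neighbour for labels. Pixels outside the volume get
#' the background value (minimum intensity, or 0 for labels).
#'
#' @param p a `preprocessed_volume`, or a 3D array on the same cube grid.
#' @param plane a `plane_spec`.
#' @param mode `"intensity"` or `"label"`.
#' @return An object of class `slice_2d`: `data` (height x width matrix,
#'   rows increase inferiorly), `plane`, `mode`.
#' @export
extract_slice <- function(p, plane, mode = c("intensity", "label")) {
  mode <- match.arg(mode)
  arr <- if (inherits(p, "preprocessed_volume")) p$data else p
  stopifnot(length(dim(arr)) == 3L)
  pts <- plane_pixel_points(plane)
  d <- dim(arr)
  inside <- pts[, 1] > -0.5 & pts[, 1] < d[1] - 0.5 &
    pts[, 2] > -0.5 & pts[, 2] < d[2] - 0.5 &
    pts[, 3] > -0.5 & pts[, 3] < d[3] - 0.5
  if (!any(inside)) stop("plane does not intersect the volume", call. = FALSE)
  vals <- if (mode == "intensity") {
    trilinear_sample(arr, pts, background = min(arr))
  } else {
    nearest_sample(arr, pts, background = 0)
  }
  slice_2d(matrix(vals, nrow = plane$size[2], ncol = plane$size[1]),
           plane, mode)
}

#' @rdname extract_slice
#' @param data height x width numeric matrix.
#' @export
slice_2d <- function(data, plane, mode = "intensity") {
  stopifnot(is.matrix(data), inherits(plane, "plane_spec"),
            all(dim(data) == rev(plane$size)))
  structure(list(data = data, plane = plane, mode = mode),
            class = "slice_2d")
}

#' @export
print.slice_2d <- function(x, ...) {
  cat("<slice_2d> ", nrow(x$data), " rows x ", ncol(x$data), " cols (",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' Perturb a measurement plane
#'
#' Applies the sensitivity-experiment transforms: a PC shift along the
#' (unperturbed) plane normal, then a rotation of the frame about the
#' in-plane left-right axis (`sagittal_deg`, i.e. a pitch error) followed by
#' a rotation about the in-plane superior axis (`axial_deg`), both pivoting
#' at the plane origin. The frame is re-orthonormalized.
#'
#' @param plane a `plane_spec`.
#' @param pc_shift signed shift in cube voxels along the normal
#'   (positive = anterior at baseline).
#' @param sagittal_deg,axial_deg signed rotations in degrees.
#' @return The perturbed `plane_spec`.
#' @export
perturb_plane <- function(plane, pc_shift = 0, sagittal_deg = 0,
                          axial_deg = 0) {
  stopifnot(inherits(plane, "plane_spec"))
  if (pc_shift == 0 && sagittal_deg == 0 && axial_deg == 0) return(plane)
  origin <- plane$origin + pc_shift * plane$normal
  n <- plane$normal; u <- plane$u_axis; v <- plane$v_axis
  if (sagittal_deg != 0) {
    n <- rotate3(n, u, sagittal_deg)
    v <- rotate3(v, u, sagittal_deg)
  }
  if (axial_deg != 0) {
    n <- rotate3(n, v, axial_deg)
    u <- rotate3(u, v, axial_deg)
  }
  # Gram-Schmidt re-orthonormalization (guards accumulated rounding)
  n <- unit(n)
  u <- unit(u - sum(u * n) * n)
  v <- unit(v - sum(v * n) * n - sum(v * u) * u)
  plane_spec(origin = origin, normal = n, u_axis = u, v_axis = v,
             size = plane$size, spacing = plane$spacing)
}

#' Export a slice as an 8-bit PNG
#'
#' Intensities are min-max scaled to \[0, 1\]; label slices are written with
#' the label value in the low bits (0/1/2 out of 255).
#'
#' @param slice a `slice_2d`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice, path) {
  m <- slice$data
  img <- if (identical(slice$mode, "label")) {
    m / 255
  } else {
    rng <- range(m)
    if (diff(rng) < .Machine$double.eps) m * 0 else (m - rng[1]) / diff(rng)
  }
  png::writePNG(img, path)
  invisible(path)
}
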