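# Synthetic wedge phantoms with analytic ground truth.
#
# Each "ventricle" is a parallelogram-shaped wedge: its medial edge descends
# from a point near the apex at +/- apex_angle/2 from vertical, and the body
# extends laterally by `ventricle_width` measured perpendicular to the
# medial edge. The two medial edges are separated horizontally by `gap` at
# apex level, so the ground-truth callosal angle equals `apex_angle_deg` by
# construction.
#
# The 3D phantom extrudes this cross-section along the anterior-posterior
# axis. Mimicking the anatomy (the ventricular cross-section changes shape
# along the AC-PC axis, which is why PC mislocalization biases the CA), the
# apex angle varies smoothly with the anterior coordinate y:
#   apex(y) = apex_angle_deg + angle_mod_amp * (cos((y - y_pc)/angle_mod_len) - 1)
# which equals the nominal angle exactly at the PC and narrows away from it;
# the width also drifts slowly. AC and PC sit on the extrusion axis 26
# voxels apart (a typical AC-PC distance at 1 mm spacing).

#' Specify a wedge phantom
#'
#' @param apex_angle_deg ground-truth callosal angle (degrees, in
#'   (20, 170)).
#' @param apex_position 2D apex location `(x, y)` in slice pixels
#'   (y increases inferiorly). Default centers the apex in a 224 px slice.
#' @param wall_length medial wall length (px).
#' @param ventricle_width horizontal thickness of the wedge body lateral
#'   of the medial edge (px).
#' @param gap horizontal separation of the two medial edges at apex level
#'   (px).
#' @param noise_sd Gaussian intensity noise standard deviation (intensity
#'   units; the noiseless image has contrast 1).
#' @param tilt_sagittal_deg,tilt_axial_deg rigid rotation of the 3D phantom
#'   (volume and landmarks jointly) about the left-right and superior axes.
#' @param angle_mod_amp,angle_mod_len amplitude (degrees) and length scale
#'   (voxels) of the smooth apex-angle variation along the
#'   anterior-posterior axis of the 3D phantom.
#' @param width_slope linear drift of the ventricle width per voxel along
#'   the extrusion axis.
#' @param roof_slope downward slope of the wedge roof per pixel of lateral
#'   distance from the medial corner (the ventricular roof is highest at
#'   the midline); keeps the most superior inter-ventricular contact at
#'   the medial corner.
#' @param seed integer RNG seed for the intensity noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(apex_angle_deg = 90,
                         apex_position = c(112.3, 60.7),
                         wall_length = 95,
                         ventricle_width = 18,
                         gap = 6,
                         noise_sd = 0,
                         tilt_sagittal_deg = 0,
                         tilt_axial_deg = 0,
                         angle_mod_amp = 16,
                         angle_mod_len = 8,
                         width_slope = 0.04,
                         roof_slope = 0.15,
                         seed = 1L) {
  if (apex_angle_deg <= 20 || apex_angle_deg >= 170) {
    stop("apex_angle_deg must lie in (20, 170)", call. = FALSE)
  }
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  if (wall_length < 20) stop("wall_length must be >= 20 px", call. = FALSE)
  structure(
    list(apex_angle_deg = apex_angle_deg,
         apex_position = as.numeric(apex_position),
         wall_length = wall_length, ventricle_width = ventricle_width,
         gap = gap, noise_sd = noise_sd,
         tilt_sagittal_deg = tilt_sagittal_deg,
         tilt_axial_deg = tilt_axial_deg,
         angle_mod_amp = angle_mod_amp, angle_mod_len = angle_mod_len,
         width_slope = width_slope, roof_slope = roof_slope,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Membership of 2D points in one wedge. `sgn` = -1 for the (anatomical)
# left ventricle (low x), +1 for the right. The wedge is the slanted band
# of horizontal thickness `width` lying laterally of the medial edge and
# inferior to apex level, so the midline-facing boundary is exactly the
# medial wall (nothing of the body rises above the apex or faces the
# midline more steeply than the wall). Vectorized over points; beta
# (half-angle, radians) and width may be per-point vectors (3D tapering).
wedge_membership <- function(x, y, apex, beta, width, gap, wall_length,
                             sgn, roof_slope = 0.15) {
  # top medial corner of this side
  mx <- apex[1] + sgn * gap / 2
  my <- apex[2]
  depth <- y - my                         # inferior distance below the apex
  medial_x <- mx + sgn * tan(beta) * depth
  b <- sgn * (x - medial_x)               # lateral of the medial edge
  # the roof is flat for the first 2 px beside the medial corner (keeps the
  # rasterized apex connected at any wall slope), then drops laterally
  depth >= roof_slope * pmax(b - 2, 0) & depth <= wall_length * cos(beta) &
    b >= 0 & b <= width
}

#' Generate a 2D wedge slice phantom
#'
#' Builds the analytic multiclass mask on a 224 x 224 pixel grid (or the
#' grid of `size`), an intensity image (lightly smoothed mask plus seeded
#' Gaussian noise), and the analytic ground-truth wall lines.
#'
#' @param spec a [phantom_spec()].
#' @param size slice size in pixels (width, height).
#' @return A list with `slice` ([slice_2d()] intensity), `mask`
#'   ([ventricle_mask()]), `truth` (list: `angle_deg`, `left_wall`,
#'   `right_wall` as `wall_line` objects, `apex`).
#' @export
make_wedge_slice <- function(spec, size = c(224L, 224L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- as.integer(size[1]); h <- as.integer(size[2])
  beta <- deg2rad(spec$apex_angle_deg) / 2
  check_wedge_inside(spec, w, h)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  left <- wedge_membership(xs, ys, spec$apex_position, beta,
                           spec$ventricle_width, spec$gap,
                           spec$wall_length, sgn = -1,
                           roof_slope = spec$roof_slope)
  right <- wedge_membership(xs, ys, spec$apex_position, beta,
                            spec$ventricle_width, spec$gap,
                            spec$wall_length, sgn = +1,
                            roof_slope = spec$roof_slope)
  labels <- matrix(0L, nrow = h, ncol = w)
  labels[left] <- 1L
  labels[right] <- 2L
  mask <- ventricle_mask(labels, spacing = 1)

  intensity <- smooth2d(0.1 + 0.9 * (labels > 0))
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed, {
      matrix(stats::rnorm(h * w, sd = spec$noise_sd), nrow = h)
    })
    intensity <- intensity + noise
  }
  # identity plane so the slice carries a well-formed geometry
  plane <- plane_spec(origin = c((w %/% 2), 64, (h %/% 2)),
                      normal = c(0, 1, 0), u_axis = c(1, 0, 0),
                      v_axis = c(0, 0, 1), size = c(w, h), spacing = 1)
  slice <- slice_2d(intensity, plane, mode = "intensity")

  truth <- wedge_truth(spec, beta)
  list(slice = slice, mask = mask, truth = truth)
}

wedge_truth <- function(spec, beta) {
  base_l <- c(spec$apex_position[1] - spec$gap / 2, spec$apex_position[2])
  base_r <- c(spec$apex_position[1] + spec$gap / 2, spec$apex_position[2])
  wl <- structure(list(base_point = base_l,
                       direction = c(-sin(beta), cos(beta)),
                       inlier_count = NA_integer_, inlier_rms = 0,
                       angle_from_vertical_deg = -rad2deg(beta)),
                  class = "wall_line")
  wr <- structure(list(base_point = base_r,
                       direction = c(sin(beta), cos(beta)),
                       inlier_count = NA_integer_, inlier_rms = 0,
                       angle_from_vertical_deg = rad2deg(beta)),
                  class = "wall_line")
  list(angle_deg = spec$apex_angle_deg, left_wall = wl, right_wall = wr,
       apex = spec$apex_position)
}

check_wedge_inside <- function(spec, w, h) {
  beta <- deg2rad(spec$apex_angle_deg) / 2
  corners <- wedge_corners(spec$apex_position, beta, spec$ventricle_width,
                           spec$gap, spec$wall_length)
  if (any(corners[, 1] < 0) || any(corners[, 1] > w - 1) ||
      any(corners[, 2] < 0) || any(corners[, 2] > h - 1)) {
    stop("phantom walls exit the image; shrink wall_length/ventricle_width ",
         "or move the apex", call. = FALSE)
  }
  invisible(corners)
}

wedge_corners <- function(apex, beta, width, gap, wall_length) {
  out <- NULL
  h <- wall_length * cos(beta)
  for (sgn in c(-1, 1)) {
    m1 <- c(apex[1] + sgn * gap / 2, apex[2])
    m2 <- m1 + c(sgn * tan(beta) * h, h)
    out <- rbind(out, m1, m2, m1 + c(sgn * width, 0), m2 + c(sgn * width, 0))
  }
  out
}

# light 3x3 binomial smoothing, edge-replicated
smooth2d <- function(m) {
  pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  i <- 2:(nrow(pad) - 1); j <- 2:(ncol(pad) - 1)
  (4 * pad[i, j] +
     2 * (pad[i - 1, j] + pad[i + 1, j] + pad[i, j - 1] + pad[i, j + 1]) +
     pad[i - 1, j - 1] + pad[i - 1, j + 1] + pad[i + 1, j - 1] +
     pad[i + 1, j + 1]) / 16
}

#' Generate a 3D wedge phantom volume
#'
#' Extrudes the 2D wedge along the anterior-posterior axis with a smoothly
#' varying apex angle and width (see the module notes above), embeds it in
#' an isotropic RAS volume, optionally applies a rigid tilt (to volume and
#' landmarks jointly), and returns the analytic AC/PC landmarks.
#'
#' @param spec a [phantom_spec()]. The 2D geometry fields are interpreted
#'   in cube voxels; defaults suited to a 128-cube are applied when the
#'   spec still carries the 224-slice defaults.
#' @param shape volume dimensions (default `c(128, 128, 128)`).
#' @param ap_extent anterior-posterior extent `(y_min, y_max)` of the
#'   extrusion (voxels).
#' @param acpc_distance AC-PC distance along the extrusion axis (voxels,
#'   default 26).
#' @return A list with `volume` ([volume_grid()] intensity, 1 mm iso
#'   affine), `labels` (3D integer array on the same grid), `truth` (list
#'   with `world_ac`, `world_pc`, `angle_deg`, `pivot`, `rotation`), and
#'   `spec` (the effective 3D spec).
#' @export
make_phantom_volume <- function(spec, shape = c(128L, 128L, 128L),
                                ap_extent = c(36, 94),
                                acpc_distance = 26) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec3 <- spec
  # rescale the 224-px 2D defaults to the 128-cube cross-section
  if (identical(spec$apex_position, c(112.3, 60.7)) && spec$wall_length == 95) {
    spec3$apex_position <- c(64.3, 42.7)  # apex off-lattice, z ~ 84.3
    # lateral reach is capped at 40 voxels, so narrower angles get the
    # longer, steeper walls seen in real ventricles
    spec3$wall_length <- min(80, 40 / sin(deg2rad(spec$apex_angle_deg) / 2))
    spec3$ventricle_width <- 12
  }
  shape <- as.integer(shape)
  y_pc <- 64 - acpc_distance / 2   # PC posterior, AC anterior
  y_ac <- 64 + acpc_distance / 2
  beta0 <- deg2rad(spec3$apex_angle_deg) / 2

  # voxel-center coordinates (0-based); x = right, y = anterior, z = superior
  xs <- seq_len(shape[1]) - 1
  ys <- seq_len(shape[2]) - 1
  zs <- seq_len(shape[3]) - 1
  grid <- cbind(rep(xs, times = shape[2] * shape[3]),
                rep(rep(ys, each = shape[1]), times = shape[3]),
                rep(zs, each = shape[1] * shape[2]))

  pivot <- (shape - 1) / 2
  tilt <- spec3$tilt_sagittal_deg != 0 || spec3$tilt_axial_deg != 0
  if (tilt) {
    # solid is the rigidly rotated base solid: pull coordinates back
    q <- sweep(grid, 2, pivot)
    q <- rotate3(q, c(0, 0, 1), -spec3$tilt_axial_deg)
    q <- rotate3(q, c(1, 0, 0), -spec3$tilt_sagittal_deg)
    q <- sweep(q, 2, pivot, FUN = "+")
  } else {
    q <- grid
  }

  yy <- q[, 2]
  in_slab <- yy >= ap_extent[1] & yy <= ap_extent[2]
  apex_deg <- spec3$apex_angle_deg + spec3$angle_mod_amp *
    (cos((yy - y_pc) / spec3$angle_mod_len) - 1)
  beta <- deg2rad(pmax(apex_deg, 21)) / 2
  width <- pmax(2, spec3$ventricle_width +
                  spec3$width_slope * (yy - y_pc))
  # slice-plane 2D coordinates of each voxel: x2 = x, y2 = (top row) - z
  x2 <- q[, 1]
  y2 <- (shape[3] - 1) - q[, 3]
  left <- in_slab & wedge_membership(x2, y2, spec3$apex_position, beta,
                                     width, spec3$gap, spec3$wall_length,
                                     sgn = -1, roof_slope = spec3$roof_slope)
  right <- in_slab & wedge_membership(x2, y2, spec3$apex_position, beta,
                                      width, spec3$gap, spec3$wall_length,
                                      sgn = +1, roof_slope = spec3$roof_slope)
  labels <- array(0L, dim = shape)
  labels[left] <- 1L
  labels[right] <- 2L

  intensity <- array(0.1, dim = shape)
  intensity[labels > 0L] <- 1
  if (spec3$noise_sd > 0) {
    intensity <- intensity + withr::with_seed(spec3$seed, {
      array(stats::rnorm(prod(shape), sd = spec3$noise_sd), dim = shape)
    })
  }

  # landmarks on the extrusion axis at apex height, rotated with the volume
  apex_z <- (shape[3] - 1) - spec3$apex_position[2]
  ac <- c(spec3$apex_position[1], y_ac, apex_z)
  pc <- c(spec3$apex_position[1], y_pc, apex_z)
  rot <- function(p) {
    p <- p - pivot
    p <- rotate3(p, c(1, 0, 0), spec3$tilt_sagittal_deg)
    p <- rotate3(p, c(0, 0, 1), spec3$tilt_axial_deg)
    p + pivot
  }
  world_ac <- if (tilt) rot(ac) else ac
  world_pc <- if (tilt) rot(pc) else pc

  check_phantom_inside(labels)

  affine <- diag(4)  # 1 mm isotropic, origin at voxel (0,0,0)
  list(
    volume = volume_grid(intensity, affine),
    labels = labels,
    truth = list(world_ac = world_ac, world_pc = world_pc,
                 angle_deg = spec3$apex_angle_deg, pivot = pivot,
                 y_pc = y_pc, ap_extent = ap_extent),
    spec = spec3
  )
}

check_phantom_inside <- function(labels) {
  d <- dim(labels)
  touches <-
    any(labels[1, , ] > 0) || any(labels[d[1], , ] > 0) ||
    any(labels[, 1, ] > 0) || any(labels[, d[2], ] > 0) ||
    any(labels[, , 1] > 0) || any(labels[, , d[3]] > 0)
  if (touches) {
    stop("phantom ventricles exit the volume (tilt or geometry too large)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Analytic phantom segmenter
#'
#' Returns a segmenter (see [file_segmenter()] for the contract) that
#' rasterizes the phantom's analytic ventricle solids on the pixel grid of
#' whatever plane is being segmented — the synthetic stand-in for the
#' trained segmentation network, exact up to pixel rasterization.
#'
#' @param phantom the list returned by [make_phantom_volume()].
#' @return A function `(slice_2d, preprocessed_volume) -> ventricle_mask`.
#' @export
phantom_segmenter <- function(phantom) {
  force(phantom)
  function(slice, pre) {
    pts_cube <- plane_pixel_points(slice$plane)
    # cube -> source voxel coordinates of the phantom volume
    pts <- cube_to_source_voxel(pre, pts_cube)
    spec3 <- phantom$spec
    shape <- dim(phantom$labels)
    pivot <- phantom$truth$pivot
    if (spec3$tilt_sagittal_deg != 0 || spec3$tilt_axial_deg != 0) {
      q <- sweep(pts, 2, pivot)
      q <- rotate3(q, c(0, 0, 1), -spec3$tilt_axial_deg)
      q <- rotate3(q, c(1, 0, 0), -spec3$tilt_sagittal_deg)
      pts <- sweep(q, 2, pivot, FUN = "+")
    }
    yy <- pts[, 2]
    y_pc <- phantom$truth$y_pc
    apex_deg <- spec3$apex_angle_deg + spec3$angle_mod_amp *
      (cos((yy - y_pc) / spec3$angle_mod_len) - 1)
    beta <- deg2rad(pmax(apex_deg, 21)) / 2
    width <- pmax(2, spec3$ventricle_width +
                    spec3$width_slope * (yy - y_pc))
    x2 <- pts[, 1]
    y2 <- (shape[3] - 1) - pts[, 3]
    in_slab <- yy >= phantom$truth$ap_extent[1] &
      yy <= phantom$truth$ap_extent[2]
    left <- in_slab & wedge_membership(x2, y2, spec3$apex_position, beta,
                                       width, spec3$gap, spec3$wall_length,
                                       sgn = -1,
                                       roof_slope = spec3$roof_slope)
    right <- in_slab & wedge_membership(x2, y2, spec3$apex_position, beta,
                                        width, spec3$gap, spec3$wall_length,
                                        sgn = +1,
                                        roof_slope = spec3$roof_slope)
    labels <- matrix(0L, nrow = slice$plane$size[2],
                     ncol = slice$plane$size[1])
    labels[left] <- 1L
    labels[right] <- 2L
    ventricle_mask(labels, spacing = slice$plane$spacing)
  }
}
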