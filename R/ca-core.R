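# Core callosal-angle geometry: maximum-margin separating line between the
# two ventricle contours, perpendicular ray casting onto the medial walls,
# base-point identification, inlier-maximizing wall-line search, and the
# angle between the two wall lines.
#
# All operations work in slice pixel coordinates (x = column, y = row,
# y increasing inferiorly). "Inferior-oriented" direction vectors have a
# non-negative y component.

#' Measurement configuration
#'
#' Bundles every tunable of the measurement geometry; the effective values
#' are echoed into every result for reproducibility.
#'
#' @param ray_step spacing of perpendicular rays along the separating line,
#'   in pixels.
#' @param wall_tol inlier distance tolerance of the wall-line search (px).
#' @param angular_step direction sweep resolution of the wall-line search
#'   (degrees).
#' @param base_threshold inter-ventricle distance threshold for base-point
#'   candidates (px); a floor of `d_min + 1` px always applies, where
#'   `d_min` is the minimal inter-contour distance.
#' @param classify_threshold angle (degrees) below which a CA is classified
#'   "narrow" (strict `<`; exactly the threshold is "wide").
#' @param min_px smallest acceptable ventricle region (px).
#' @param edge preprocessing cube edge (voxels).
#' @param slice_size,slice_spacing slice geometry passed to [build_plane()].
#'   The default spacing `edge / 224` makes the 224 x 224 slice span the
#'   full cube field of view, i.e. the coronal section resized to the
#'   segmenter's input size.
#' @return A named list of class `ca_config`.
#' @export
ca_config <- function(ray_step = 1, wall_tol = 1.5, angular_step = 0.25,
                      base_threshold = 5, classify_threshold = 90,
                      min_px = 5L, edge = 128L,
                      slice_size = c(224L, 224L),
                      slice_spacing = edge / 224) {
  structure(
    list(ray_step = ray_step, wall_tol = wall_tol,
         angular_step = angular_step, base_threshold = base_threshold,
         classify_threshold = classify_threshold, min_px = as.integer(min_px),
         edge = as.integer(edge), slice_size = as.integer(slice_size),
         slice_spacing = slice_spacing),
    class = "ca_config"
  )
}

#' Maximum-margin separating line between the two ventricles
#'
#' For separable contours the exact hard-margin solution is computed from
#' the closest pair of points between the convex hulls of the two contours:
#' the optimal separator is the perpendicular bisector of the shortest
#' hull-to-hull segment, and the margin is half its length. When the hulls
#' intersect (but the overlap is below 20% of the smaller contour area) a
#' most-separating fallback line is found by a deterministic sweep over
#' directions, maximizing the (possibly negative) worst-case signed
#' clearance.
#'
#' @param left,right `ventricle_contour` objects.
#' @return An object of class `separating_line`: `point` (on the line),
#'   `direction` (unit, oriented with non-negative y), `margin` (px, >= 0
#'   for separable input), `soft` (TRUE if the fallback was used).
#' @export
fit_separating_line <- function(left, right) {
  pl <- if (inherits(left, "ventricle_contour")) left$points else as.matrix(left)
  pr <- if (inherits(right, "ventricle_contour")) right$points else as.matrix(right)
  if (nrow(pl) == 0L || nrow(pr) == 0L) {
    stop("empty contour", call. = FALSE)
  }
  hl <- hull_points(pl)
  hr <- hull_points(pr)
  cp <- hull_closest_pair(hl, hr)
  if (cp$distance > 1e-9 && !hulls_intersect(hl, hr)) {
    nrm <- (cp$q - cp$p) / cp$distance       # unit normal, left -> right
    mid <- (cp$p + cp$q) / 2
    dir <- c(-nrm[2], nrm[1])
    if (dir[2] < 0 || (dir[2] == 0 && dir[1] < 0)) dir <- -dir
    return(structure(
      list(point = mid, direction = dir, margin = cp$distance / 2,
           soft = FALSE),
      class = "separating_line"
    ))
  }
  # overlapping hulls: quantify overlap, then fall back to a direction sweep
  area_l <- abs(shoelace_area(pl)); area_r <- abs(shoelace_area(pr))
  smaller <- min(area_l, area_r)
  frac <- contour_overlap_fraction(pl, pr) / max(smaller, 1e-9)
  if (frac > 0.20) {
    stop("ventricles not separable: contours overlap by ",
         sprintf("%.0f%%", 100 * frac), " of the smaller area",
         call. = FALSE)
  }
  sweep <- soft_margin_sweep(pl, pr)
  structure(
    list(point = sweep$point, direction = sweep$direction,
         margin = max(0, sweep$margin), soft = TRUE),
    class = "separating_line"
  )
}

#' @export
print.separating_line <- function(x, ...) {
  cat("<separating_line> through (",
      paste(signif(x$point, 5), collapse = ", "), "), direction (",
      paste(signif(x$direction, 4), collapse = ", "), "), margin ",
      signif(x$margin, 4), " px", if (x$soft) " (soft fallback)" else "",
      "\n", sep = "")
  invisible(x)
}

# Resample a closed polyline at roughly `step` px spacing (vertices kept).
resample_polyline <- function(pts, step = 0.25) {
  n <- nrow(pts)
  if (n < 2L) return(pts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- pts[i, ]
    b <- pts[if (i == n) 1L else i + 1L, ]
    len <- vnorm(b - a)
    k <- max(1L, ceiling(len / step))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

hull_points <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

# Closest pair of points between two convex polygons (vertex-to-edge scans
# in both directions; covers vertex-vertex and parallel-edge cases).
hull_closest_pair <- function(a, b) {
  best <- list(distance = Inf, p = NULL, q = NULL)
  scan <- function(verts, poly, swap) {
    n <- nrow(poly)
    for (i in seq_len(n)) {
      s1 <- poly[i, ]
      s2 <- poly[if (i == n) 1L else i + 1L, ]
      for (v in seq_len(nrow(verts))) {
        cp <- closest_point_on_segment(verts[v, ], s1, s2)
        if (cp$distance < best$distance) {
          best <<- if (swap) {
            list(distance = cp$distance, p = cp$point, q = verts[v, ])
          } else {
            list(distance = cp$distance, p = verts[v, ], q = cp$point)
          }
        }
      }
    }
  }
  scan(a, b, swap = FALSE)  # p on hull a, q on hull b
  scan(b, a, swap = TRUE)
  best
}

hulls_intersect <- function(a, b) {
  any(points_in_polygon(a, b)) || any(points_in_polygon(b, a))
}

# Monte-Carlo-free overlap area estimate: fraction of a regular grid over
# the bounding-box intersection that falls inside both contour polygons.
contour_overlap_fraction <- function(pl, pr) {
  lo <- pmax(apply(pl, 2, min), apply(pr, 2, min))
  hi <- pmin(apply(pl, 2, max), apply(pr, 2, max))
  if (any(hi <= lo)) return(0)
  nx <- max(2L, min(80L, ceiling(hi[1] - lo[1]) * 2L))
  ny <- max(2L, min(80L, ceiling(hi[2] - lo[2]) * 2L))
  gx <- seq(lo[1], hi[1], length.out = nx)
  gy <- seq(lo[2], hi[2], length.out = ny)
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  inl <- points_in_polygon(grid, rbind(pl, pl[1, ]))
  inr <- points_in_polygon(grid, rbind(pr, pr[1, ]))
  sum(inl & inr) * cell
}

# Deterministic most-separating line for non-separable input: sweep the
# normal direction; per direction the best offset is the midpoint between
# the extreme projections, giving signed clearance
# (min proj_right - max proj_left) / 2.
soft_margin_sweep <- function(pl, pr, step_deg = 0.1) {
  thetas <- seq(0, 180 - step_deg, by = step_deg)
  best <- list(value = -Inf)
  for (th in thetas) {
    nrm <- c(cos(deg2rad(th)), sin(deg2rad(th)))
    ql <- pl[, 1] * nrm[1] + pl[, 2] * nrm[2]
    qr <- pr[, 1] * nrm[1] + pr[, 2] * nrm[2]
    v1 <- (min(qr) - max(ql)) / 2
    v2 <- (min(ql) - max(qr)) / 2  # orientation with right on the low side
    v <- max(v1, v2)
    if (v > best$value) {
      sgn <- if (v1 >= v2) 1 else -1
      off <- if (v1 >= v2) (max(ql) + min(qr)) / 2 else (max(qr) + min(ql)) / 2
      best <- list(value = v, normal = sgn * nrm, offset = off * 1)
      best$point <- nrm * off
    }
  }
  dir <- c(-best$normal[2], best$normal[1])
  if (dir[2] < 0 || (dir[2] == 0 && dir[1] < 0)) dir <- -dir
  list(point = best$point, direction = dir, margin = best$value)
}

#' Cast perpendicular rays onto the medial walls
#'
#' Emits rays perpendicular to the separating line at regular stations
#' along it, spanning the projected extent of both contours. Toward each
#' side, the first intersection of the ray with that side's contour polygon
#' is recorded as a medial-wall point; stations whose ray misses the
#' contour are skipped.
#'
#' @param line a `separating_line`.
#' @param left,right `ventricle_contour` objects.
#' @param step station spacing along the line (px, default 1).
#' @return A list with elements `left` and `right` of class `medial_wall`:
#'   `points` (n x 2), `side`, `ray_index`.
#' @export
cast_medial_rays <- function(line, left, right, step = 1) {
  stopifnot(inherits(line, "separating_line"))
  pl <- contour_polygon(left)
  pr <- contour_polygon(right)
  dir <- line$direction
  perp <- c(dir[2], -dir[1])
  all_pts <- rbind(left$points, right$points)
  tproj <- (all_pts[, 1] - line$point[1]) * dir[1] +
    (all_pts[, 2] - line$point[2]) * dir[2]
  stations <- seq(min(tproj), max(tproj), by = step)
  walls <- lapply(list(left = left, right = right), function(contour) {
    poly <- contour_polygon(contour)
    centroid <- colMeans(contour$points)
    side_sign <- sign((centroid[1] - line$point[1]) * perp[1] +
                        (centroid[2] - line$point[2]) * perp[2])
    if (side_sign == 0) side_sign <- 1
    ray_dir <- side_sign * perp
    hits <- matrix(numeric(0), ncol = 2)
    ray_idx <- integer(0)
    for (k in seq_along(stations)) {
      s0 <- line$point + stations[k] * dir
      t_hit <- ray_polygon_first_hit(s0, ray_dir, poly)
      if (is.finite(t_hit)) {
        hits <- rbind(hits, s0 + t_hit * ray_dir)
        ray_idx <- c(ray_idx, k)
      }
    }
    structure(
      list(points = hits, side = class_name(contour$class_id),
           ray_index = ray_idx),
      class = "medial_wall"
    )
  })
  for (w in walls) {
    if (nrow(w$points) < 3L) {
      stop("medial wall too short: only ", nrow(w$points),
           " ray hits on the ", w$side, " side", call. = FALSE)
    }
  }
  walls
}

#' @export
print.medial_wall <- function(x, ...) {
  cat("<medial_wall> ", x$side, ", ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

# Smallest t >= 0 with origin + t*dir on the polygon boundary (Inf if none).
# Vectorized over the polygon edges.
ray_polygon_first_hit <- function(origin, dir, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- dir[1] * (-ey) - dir[2] * (-ex)   # cross(dir, -edge)
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  ok <- abs(denom) > 1e-12
  t <- (wx * (-ey) - wy * (-ex)) / denom     # along the ray
  s <- (dir[1] * wy - dir[2] * wx) / denom   # along the edge
  valid <- ok & t >= -1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(valid)) return(Inf)
  max(0, min(t[valid]))
}

#' Identify the base points of the medial walls
#'
#' For each ventricle, among its contour points whose distance to the other
#' contour is at most `max(threshold, d_min + 1)` px (`d_min` being the
#' minimal inter-contour distance, so candidates always exist), the most
#' superior point (smallest row coordinate) is returned. Ties on row are
#' broken by smaller distance to the other contour, then by the medial-most
#' point.
#'
#' @param left,right `ventricle_contour` objects.
#' @param threshold base-point distance threshold (px, default 5).
#' @return A list with `left` and `right` 2D points.
#' @export
find_base_points <- function(left, right, threshold = 5) {
  # candidates live on the contour polyline, not only at its vertices:
  # resample densely so the base point is not biased by vertex placement
  pl <- resample_polyline(left$points, step = 0.25)
  pr <- resample_polyline(right$points, step = 0.25)
  d <- cross_distances(pl, pr)
  d_min <- min(d)
  thr <- max(threshold, d_min + 1)
  pick <- function(pts, dist_other, medial_sign) {
    cand <- which(dist_other <= thr)
    ord <- order(pts[cand, 2], dist_other[cand], -medial_sign * pts[cand, 1])
    pts[cand[ord[1]], ]
  }
  list(left = pick(pl, apply(d, 1, min), medial_sign = +1),
       right = pick(pr, apply(d, 2, min), medial_sign = -1))
}

#' Fit the medial-wall line through a base point
#'
#' Sweeps directions through the base point at `angular_step` resolution
#' over (-90, 90] degrees from vertical and returns the direction whose
#' line has the most wall points within `tol`. Ties are broken by minimal
#' RMS distance of the inliers, then by the smaller absolute angle from
#' vertical, then by the smaller signed angle. The returned direction is
#' oriented inferiorly.
#'
#' @param base 2D base point.
#' @param wall a `medial_wall` (>= 3 points).
#' @param tol inlier tolerance (px, default 1.5).
#' @param angular_step sweep resolution (degrees, default 0.25).
#' @return An object of class `wall_line`: `base_point`, `direction` (unit,
#'   inferior-oriented), `inlier_count`, `inlier_rms`,
#'   `angle_from_vertical_deg` (signed, positive toward subject right).
#' @export
fit_wall_line <- function(base, wall, tol = 1.5, angular_step = 0.25) {
  pts <- if (inherits(wall, "medial_wall")) wall$points else as.matrix(wall)
  if (nrow(pts) < 3L) {
    stop("need at least 3 medial-wall points", call. = FALSE)
  }
  thetas <- seq(-90 + angular_step, 90, by = angular_step)
  sweep <- wall_sweep(base, pts, tol, thetas)
  if (sweep$count < 3L) {
    stop("no linear wall: best direction has only ", sweep$count,
         " inliers", call. = FALSE)
  }
  dir <- c(sin(deg2rad(sweep$theta)), cos(deg2rad(sweep$theta)))
  structure(
    list(base_point = as.numeric(base), direction = dir,
         inlier_count = sweep$count, inlier_rms = sweep$rms,
         angle_from_vertical_deg = sweep$theta),
    class = "wall_line"
  )
}

#' @export
print.wall_line <- function(x, ...) {
  cat("<wall_line> base (", paste(signif(x$base_point, 5), collapse = ", "),
      "), ", signif(x$angle_from_vertical_deg, 4),
      " deg from vertical, ", x$inlier_count, " inliers (rms ",
      signif(x$inlier_rms, 3), " px)\n", sep = "")
  invisible(x)
}

# Shared sweep core (also used by the fine-resolution oracle in tests).
wall_sweep <- function(base, pts, tol, thetas) {
  dx <- pts[, 1] - base[1]
  dy <- pts[, 2] - base[2]
  th <- deg2rad(thetas)
  # distance of each point to the line through base with direction theta:
  # |cos(th)*dx - sin(th)*dy|
  dist <- abs(outer(cos(th), dx) - outer(sin(th), dy))
  inl <- dist <= tol
  counts <- rowSums(inl)
  rms <- vapply(seq_along(thetas), function(i) {
    if (counts[i] == 0L) return(Inf)
    sqrt(mean(dist[i, inl[i, ]]^2))
  }, numeric(1))
  ord <- order(-counts, rms, abs(thetas), thetas)
  i <- ord[1]
  list(theta = thetas[i], count = counts[i], rms = rms[i])
}

#' Angle between the two medial-wall lines
#'
#' `acos` of the dot product of the two inferior-oriented unit directions,
#' in degrees. With both vectors oriented inferiorly this is the callosal
#' angle: the inferior opening between the medial walls.
#'
#' @param left,right `wall_line` objects (or unit 2-vectors).
#' @return Angle in degrees, in (0, 180).
#' @export
angle_between_walls <- function(left, right) {
  dl <- if (inherits(left, "wall_line")) left$direction else as.numeric(left)
  dr <- if (inherits(right, "wall_line")) right$direction else as.numeric(right)
  if (vnorm(dl) < 1e-12 || vnorm(dr) < 1e-12) {
    stop("zero wall direction", call. = FALSE)
  }
  rad2deg(acos(clamp(sum(unit(dl) * unit(dr)), -1, 1)))
}

#' Measure the callosal angle on a slice
#'
#' Runs the full 2D chain: contour extraction, maximum-margin separating
#' line, perpendicular ray casting, base-point identification, wall-line
#' search on each side, and the angle between the wall lines. All
#' intermediate geometry is kept on the result for audit and plotting.
#'
#' @param slice a [slice_2d()] (kept for provenance/plotting; the
#'   measurement itself uses only the mask).
#' @param mask a [ventricle_mask()] with both classes present.
#' @param config a [ca_config()].
#' @return An object of class `ca_result` with fields `angle_deg`,
#'   `classification` (`"narrow"` iff angle < threshold, else `"wide"`),
#'   `left_wall`, `right_wall`, `separating_line`, `medial_walls`,
#'   `base_points`, `contours`, `config`, `diagnostics`.
#' @export
measure_ca <- function(slice, mask, config = ca_config()) {
  stopifnot(inherits(mask, "ventricle_mask"))
  diagnostics <- character(0)
  contours <- with_stage("contours", extract_contours(mask, config$min_px))
  sep <- with_stage("separating_line",
                    fit_separating_line(contours$left, contours$right))
  if (isTRUE(sep$soft)) {
    diagnostics <- c(diagnostics,
                     "separating line used soft-margin fallback")
  }
  walls <- with_stage("medial_walls",
                      cast_medial_rays(sep, contours$left, contours$right,
                                       step = config$ray_step))
  bases <- with_stage("base_points",
                      find_base_points(contours$left, contours$right,
                                       threshold = config$base_threshold))
  wl <- with_stage("wall_line_left",
                   fit_wall_line(bases$left, walls$left,
                                 tol = config$wall_tol,
                                 angular_step = config$angular_step))
  wr <- with_stage("wall_line_right",
                   fit_wall_line(bases$right, walls$right,
                                 tol = config$wall_tol,
                                 angular_step = config$angular_step))
  angle <- with_stage("angle", angle_between_walls(wl, wr))
  structure(
    list(
      angle_deg = angle,
      classification = if (angle < config$classify_threshold) "narrow"
                       else "wide",
      left_wall = wl, right_wall = wr,
      separating_line = sep,
      medial_walls = walls,
      base_points = bases,
      contours = contours,
      slice = slice,
      config = config,
      diagnostics = diagnostics
    ),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat("<ca_result> callosal angle ", sprintf("%.2f", x$angle_deg),
      " deg (", x$classification, ")\n  wall angles from vertical: left ",
      sprintf("%.2f", x$left_wall$angle_from_vertical_deg), ", right ",
      sprintf("%.2f", x$right_wall$angle_from_vertical_deg),
      "; separating margin ", signif(x$separating_line$margin, 4), " px\n",
      sep = "")
  if (length(x$diagnostics)) {
    cat("  warnings:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}
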