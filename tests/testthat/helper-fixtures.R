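# Shared fixtures: small volumes, masks and brute-force oracles.
# Everything is generated in code; seeds are stated at each use site.

# A small intensity volume with a marked voxel, identity-scaled affine.
make_test_volume <- function(dims = c(12L, 14L, 16L), spacing = c(1, 1, 1),
                             origin = c(-5, -6, -7), seed = 42L) {
  arr <- withr::with_seed(seed, array(stats::rnorm(prod(dims)), dim = dims))
  affine <- diag(c(spacing, 1))
  affine[1:3, 4] <- origin
  volume_grid(arr, affine)
}

# Binary rectangle mask helper: rows/cols are 1-based index ranges.
rect_mask <- function(nrow, ncol, rows1, cols1, rows2 = NULL, cols2 = NULL) {
  m <- matrix(0L, nrow, ncol)
  m[rows1, cols1] <- 1L
  if (!is.null(rows2)) m[rows2, cols2] <- 2L
  ventricle_mask(m)
}

# Contour object from explicit vertices (x, y), bypassing mask tracing.
contour_from_points <- function(pts, class_id = 1L) {
  structure(list(points = as.matrix(pts), class_id = class_id,
                 closed = TRUE),
            class = "ventricle_contour")
}

separating_line_manual <- function(point, direction, margin = 0) {
  structure(list(point = point, direction = direction / sqrt(sum(direction^2)),
                 margin = margin, soft = FALSE),
            class = "separating_line")
}

# Exhaustive separating-line oracle: sweep the normal angle in `step_deg`
# increments; per angle the optimal offset is the midpoint between extreme
# projections, so the margin is (min right - max left) / 2.
margin_oracle <- function(left, right, step_deg = 0.1) {
  best <- -Inf
  for (th in seq(0, 180 - step_deg, by = step_deg)) {
    nrm <- c(cos(th * pi / 180), sin(th * pi / 180))
    ql <- left %*% nrm
    qr <- right %*% nrm
    best <- max(best, (min(qr) - max(ql)) / 2, (min(ql) - max(qr)) / 2)
  }
  best
}

# Random separable point clouds: two discs with a guaranteed gap.
separable_instance <- function(seed, n_max = 60) {
  withr::with_seed(seed, {
    n1 <- sample(5:n_max, 1); n2 <- sample(5:n_max, 1)
    ang <- stats::runif(1, 0, 2 * pi)
    gap <- stats::runif(1, 0.5, 2.5)   # inter-ventricular gaps are a few px
    r1 <- stats::runif(1, 2, 6); r2 <- stats::runif(1, 2, 6)
    centre_dist <- r1 + r2 + gap
    c1 <- c(0, 0)
    c2 <- c1 + centre_dist * c(cos(ang), sin(ang))
    sample_disc <- function(n, centre, r) {
      t <- stats::runif(n, 0, 2 * pi)
      rho <- r * sqrt(stats::runif(n))
      cbind(centre[1] + rho * cos(t), centre[2] + rho * sin(t))
    }
    list(left = sample_disc(n1, c1, r1), right = sample_disc(n2, c2, r2))
  })
}

# Noisy collinear wall instance for the wall-line sweep oracle.
wall_instance <- function(seed, n = 50, theta_deg = NULL, noise_sd = 0.5) {
  withr::with_seed(seed, {
    if (is.null(theta_deg)) theta_deg <- stats::runif(1, -60, 60)
    th <- theta_deg * pi / 180
    s <- sort(stats::runif(n, 5, 55))
    d <- c(sin(th), cos(th))
    perp <- c(cos(th), -sin(th))
    e <- stats::rnorm(n, sd = noise_sd)
    pts <- cbind(s * d[1] + e * perp[1], s * d[2] + e * perp[2])
    list(base = c(0, 0), points = pts, theta_deg = theta_deg)
  })
}

# Phantom-driven end-to-end measurement used by several suites.
measure_phantom_3d <- function(apex, tilt_sag = 0, tilt_ax = 0,
                               noise_sd = 0, seed = 1L,
                               config = ca_config()) {
  ph <- make_phantom_volume(phantom_spec(
    apex_angle_deg = apex, tilt_sagittal_deg = tilt_sag,
    tilt_axial_deg = tilt_ax, noise_sd = noise_sd, seed = seed
  ))
  run_pipeline(ph$volume, phantom_landmark_provider(ph$truth),
               phantom_segmenter(ph), config = config)
}
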