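test_that("contours trace rectangles with the right area and point count", {
  m <- rect_mask(20, 20, 5:14, 3:12, 5:14, 15:18)
  cs <- extract_contours(m)
  # shoelace area of the subpixel boundary is the pixel area within 1 px^2
  a <- abs(caliper:::shoelace_area(cs$left$points))
  expect_lt(abs(a - 100), 1)
  expect_gte(nrow(cs$left$points), 20)  # perimeter-consistent vertex count
  expect_equal(cs$left$class_id, 1L)
  expect_equal(cs$right$class_id, 2L)
})

test_that("only the largest connected component is traced", {
  m0 <- matrix(0L, 20, 20)
  m0[3:12, 3:8] <- 1L   # 60 px
  m0[16:18, 16:17] <- 1L  # 6 px satellite
  m0[3:12, 12:16] <- 2L
  m <- ventricle_mask(m0)
  cs <- extract_contours(m)
  a <- abs(caliper:::shoelace_area(cs$left$points))
  expect_lt(abs(a - 60), 2)
  # every traced point stays away from the satellite
  expect_true(all(cs$left$points[, 1] < 12))
})

test_that("missing or tiny classes raise informative errors", {
  m <- rect_mask(10, 10, 2:5, 2:5)  # no right ventricle
  expect_error(extract_contours(m), "right")
  m2 <- rect_mask(10, 10, 2:5, 2:5, 7:7, 7:8)  # 2 px right ventricle
  expect_error(suppressWarnings(extract_contours(m2)), "too small")
  expect_warning(try(extract_contours(m2), silent = TRUE), "2 px")
})

test_that("wedge-phantom contours lie on the analytic boundary", {
  sp <- phantom_spec(apex_angle_deg = 90)
  wz <- make_wedge_slice(sp)
  cs <- extract_contours(wz$mask)
  beta <- pi / 4
  # analytic left-wedge boundary: medial edge, horizontal bottom cap,
  # lateral edge, sloped roof
  m1 <- c(sp$apex_position[1] - sp$gap / 2, sp$apex_position[2])
  h <- sp$wall_length * cos(beta)
  m2 <- m1 + c(-tan(beta) * h, h)
  w <- sp$ventricle_width
  d_roof <- sp$roof_slope * (w - 2)
  quad_l <- rbind(m1, m2, m2 + c(-w, 0),
                  m1 + c(-tan(beta) * d_roof - w, d_roof), m1 + c(-2, 0))
  poly_dist <- function(pts, quad) {
    segs <- rbind(quad, quad[1, ])
    d <- rep(Inf, nrow(pts))
    for (k in seq_len(nrow(quad))) {
      d <- pmin(d, caliper:::point_segment_distance(pts, segs[k, ],
                                                    segs[k + 1, ]))
    }
    d
  }
  expect_lt(max(poly_dist(cs$left$points, quad_l)), 1.5)
  expect_lt(stats::median(poly_dist(cs$left$points, quad_l)), 1)
})

test_that("Dice follows the overlap formula with the empty-mask conventions", {
  a <- rect_mask(8, 8, 2:3, 2:3, 6:7, 6:7)
  expect_equal(dice_coefficient(a, a)$mean, 1)

  # 2 x 2 squares shifted by 1 px: overlap 2, sizes 4 and 4 -> 0.5
  b <- rect_mask(8, 8, 2:3, 3:4, 6:7, 6:7)
  expect_equal(unname(dice_coefficient(a, b)$per_class["left"]), 0.5)

  # disjoint equal-area masks
  d <- rect_mask(8, 8, 4:5, 4:5, 1:2, 1:2)
  expect_equal(unname(dice_coefficient(a, d)$per_class), c(0, 0))

  # empty-vs-empty class scores 1, empty-vs-nonempty 0
  e1 <- ventricle_mask(matrix(0L, 4, 4) + rect_mask(4, 4, 1:2, 1:2)$labels)
  e2 <- rect_mask(4, 4, 1:2, 1:2)
  dd <- dice_coefficient(e1, e2)
  expect_equal(unname(dd$per_class["right"]), 1)
  e3 <- rect_mask(4, 4, 1:2, 1:2, 3:4, 3:4)
  expect_equal(unname(dice_coefficient(e2, e3)$per_class["right"]), 0)

  expect_error(dice_coefficient(a, rect_mask(9, 8, 1:2, 1:2, 3:4, 3:4)),
               "shape")
})

test_that("Hausdorff distance matches the brute-force double loop", {
  expect_equal(hausdorff_distance(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  p <- rbind(c(0, 0), c(1, 1))
  expect_equal(hausdorff_distance(p, p), 0)

  brute <- function(a, b) {
    da <- apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
    db <- apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
    max(max(da), max(db))
  }
  withr::with_seed(13L, {
    for (i in 1:20) {
      a <- matrix(stats::rnorm(40), ncol = 2)
      b <- matrix(stats::rnorm(40, mean = 0.5), ncol = 2)
      expect_equal(hausdorff_distance(a, b), brute(a, b))
      # symmetry and linear scaling
      expect_equal(hausdorff_distance(b, a), hausdorff_distance(a, b))
      expect_equal(hausdorff_distance(3 * a, 3 * b),
                   3 * hausdorff_distance(a, b))
    }
  })
  expect_equal(hausdorff_distance(p, p, spacing = 2.5), 0)
  expect_error(hausdorff_distance(p[0, , drop = FALSE], p), "empty")
})

test_that("masks round-trip through PNG and mirror correctly", {
  m <- rect_mask(16, 16, 3:8, 2:6, 3:8, 10:14)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  m2 <- read_mask_png(path)
  expect_identical(m2$labels, m$labels)

  mm <- mirror_mask(m)
  expect_equal(sum(mm$labels == 1L), sum(m$labels == 2L))
  expect_identical(mirror_mask(mm)$labels, m$labels)

  seg <- file_segmenter(path)
  plane <- plane_spec(origin = c(8, 8, 8), normal = c(0, 1, 0),
                      u_axis = c(1, 0, 0), v_axis = c(0, 0, 1),
                      size = c(16, 16), spacing = 1)
  sl <- slice_2d(matrix(0, 16, 16), plane)
  expect_identical(seg(sl)$labels, m$labels)
})

test_that("segmentation metrics aggregate Dice and Hausdorff over cases", {
  a <- rect_mask(16, 16, 3:8, 2:6, 3:8, 10:14)
  b <- rect_mask(16, 16, 4:9, 2:6, 3:8, 10:14)
  tbl <- segmentation_metrics(list(a, a), list(a, b))
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$dice[tbl$case == 1], c(1, 1))
  s <- attr(tbl, "summary")
  expect_true(s["mdsc"] < 1 && s["mdsc"] > 0.8)
  expect_true(s["mhd"] >= 0)
})
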