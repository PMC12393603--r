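test_that("symmetric wedge masks mirror about the apex column", {
  sp <- phantom_spec(apex_angle_deg = 90, apex_position = c(112, 60.7))
  wz <- make_wedge_slice(sp)
  m <- wz$mask$labels
  cx <- sp$apex_position[1]  # mirror x -> 2*cx - x swaps the ventricles
  cols <- 2:(ncol(m))        # 0-based x in 1..223 maps onto itself
  mirrored <- m[, rev(cols)]
  swapped <- mirrored
  swapped[mirrored == 1L] <- 2L
  swapped[mirrored == 2L] <- 1L
  expect_identical(m[, cols], swapped)
})

test_that("analytic wall lines reproduce the apex angle exactly", {
  for (apex in c(60, 90, 137.5)) {
    wz <- make_wedge_slice(phantom_spec(apex_angle_deg = apex))
    expect_equal(angle_between_walls(wz$truth$left_wall,
                                     wz$truth$right_wall),
                 apex, tolerance = 1e-10)
  }
})

test_that("noiseless wedge masks yield the apex angle end to end", {
  for (apex in c(60, 100, 140)) {
    wz <- make_wedge_slice(phantom_spec(apex_angle_deg = apex))
    res <- measure_ca(wz$slice, wz$mask)
    expect_lt(abs(res$angle_deg - apex), 2)
  }
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_wedge_slice(phantom_spec(noise_sd = 0.1, seed = 123L))
  b <- make_wedge_slice(phantom_spec(noise_sd = 0.1, seed = 123L))
  expect_identical(a$slice$data, b$slice$data)
  c <- make_wedge_slice(phantom_spec(noise_sd = 0.1, seed = 124L))
  expect_false(identical(a$slice$data, c$slice$data))

  v1 <- make_phantom_volume(phantom_spec(noise_sd = 0.05, seed = 5L))
  v2 <- make_phantom_volume(phantom_spec(noise_sd = 0.05, seed = 5L))
  expect_identical(v1$volume$data, v2$volume$data)
  expect_identical(v1$labels, v2$labels)
})

test_that("phantom volumes carry consistent landmarks and labels", {
  ph <- make_phantom_volume(phantom_spec(apex_angle_deg = 90))
  expect_equal(dim(ph$labels), c(128, 128, 128))
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L, 2L))
  # AC anterior of PC by the default AC-PC distance
  expect_equal(ph$truth$world_ac[2] - ph$truth$world_pc[2], 26)
  # left ventricle on the subject's left (low x)
  idx <- which(ph$labels == 1L, arr.ind = TRUE)
  idx2 <- which(ph$labels == 2L, arr.ind = TRUE)
  expect_lt(max(idx[, 1]), min(idx2[, 1]) + 1)
})

test_that("geometry that exits the volume or image is rejected", {
  expect_error(make_wedge_slice(phantom_spec(apex_angle_deg = 140,
                                             wall_length = 200)),
               "exit")
  expect_error(make_phantom_volume(phantom_spec(apex_angle_deg = 120,
                                                apex_position = c(64, 20),
                                                wall_length = 80,
                                                ventricle_width = 30)),
               "exit")
  expect_error(phantom_spec(apex_angle_deg = 10), "apex_angle")
  expect_error(phantom_spec(gap = -1), "gap")
})

test_that("tilted phantoms keep their ground truth under the full pipeline", {
  res0 <- measure_phantom_3d(100)
  expect_lt(abs(res0$angle_deg - 100), 2)
  res <- measure_phantom_3d(100, tilt_sag = 10, tilt_ax = 5)
  expect_lt(abs(res$angle_deg - 100), 2)
  # joint rigid rotation moves the measurement by at most 1 degree
  res15 <- measure_phantom_3d(100, tilt_sag = 15)
  expect_lt(abs(res15$angle_deg - res0$angle_deg), 1)
})

test_that("the phantom segmenter matches the rasterized label volume", {
  # lattice-aligned geometry: slice pixels land exactly on voxel centers,
  # so nearest-neighbour lookup and the analytic mask must agree exactly
  ph <- make_phantom_volume(phantom_spec(apex_angle_deg = 80,
                                         apex_position = c(64, 42),
                                         wall_length = 44,
                                         ventricle_width = 12))
  pre <- resize_to_cube(ph$volume, edge = 128L)
  lm <- phantom_landmark_provider(ph$truth)(pre)
  plane <- build_plane(lm, size = c(112, 112), spacing = 1)
  sl <- extract_slice(pre, plane)
  mask_seg <- phantom_segmenter(ph)(sl, pre)
  mask_vol <- extract_slice(ph$labels, plane, mode = "label")
  expect_identical(as.integer(mask_vol$data), as.integer(mask_seg$labels))
  # contours of the two agree within a pixel (Hausdorff)
  ca <- extract_contours(mask_seg)
  cb <- extract_contours(ventricle_mask(matrix(as.integer(mask_vol$data),
                                               nrow = 112)))
  expect_lt(hausdorff_distance(ca$left, cb$left), 1)
})
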