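test_that("NIfTI round-trip preserves array and affine", {
  v <- make_test_volume(spacing = c(1, 1, 2), seed = 7L)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- load_volume(path)
  expect_equal(v2$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$affine, v$affine, tolerance = 1e-6, ignore_attr = TRUE)
  # anisotropic header is reflected on the affine diagonal
  expect_equal(diag(v2$affine)[1:3], c(1, 1, 2), tolerance = 1e-6)
})

test_that("loader rejects missing files and non-3D volumes", {
  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "missing file")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  arr4 <- array(stats::rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  RNifti::writeNifti(RNifti::asNifti(arr4), path)
  expect_error(load_volume(path), "non-3D")
  expect_error(volume_grid(matrix(0, 2, 2)), "non-3D")
})

test_that("RAS reorientation is idempotent and keeps world positions", {
  v <- make_test_volume(seed = 3L)
  expect_identical(reorient_to_ras(v)$data, v$data)  # already RAS

  # store the same volume in LPS: flip first two axes, adjust affine
  lps <- v$data[rev(seq_len(dim(v$data)[1])), rev(seq_len(dim(v$data)[2])), ]
  aff <- v$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1] * (dim(v$data)[1] - 1) +
    aff[1:3, 2] * (dim(v$data)[2] - 1)
  aff[1:3, 1] <- -aff[1:3, 1]
  aff[1:3, 2] <- -aff[1:3, 2]
  vl <- volume_grid(lps, aff)
  expect_identical(vl$axis_codes, c("L", "P", "S"))

  vr <- reorient_to_ras(vl)
  expect_identical(vr$axis_codes, c("R", "A", "S"))
  expect_equal(vr$data, v$data)
  expect_equal(vr$affine, v$affine)
  # idempotence
  expect_equal(reorient_to_ras(vr), vr)
  # world position of a marked voxel is unchanged: voxel (2,3,4) 0-based
  idx <- c(2, 3, 4)
  w_ras <- (vr$affine %*% c(idx, 1))[1:3]
  idx_lps <- c(dim(v$data)[1] - 1 - idx[1], dim(v$data)[2] - 1 - idx[2],
               idx[3])
  w_lps <- (vl$affine %*% c(idx_lps, 1))[1:3]
  expect_equal(w_ras, w_lps)
  # intensity multiset preserved exactly
  expect_identical(sort(as.vector(vr$data)), sort(as.vector(vl$data)))
})

test_that("reorientation refuses oblique affines", {
  # rotate the axes by 60 degrees about the (1,1,1) diagonal: every voxel
  # axis ends up more than 45 degrees from every canonical axis
  aff <- diag(4)
  aff[1:3, 1:3] <- t(caliper:::rotate3(diag(3), c(1, 1, 1), 60))
  v <- volume_grid(array(0, dim = c(4, 4, 4)), aff)
  expect_error(reorient_to_ras(v), "oblique|ambiguous")
})

test_that("cube resize preserves aspect ratio and records the transform", {
  # identity case: 128-cube of 1 mm voxels passes through untouched
  arr <- withr::with_seed(1L, array(stats::rnorm(64^3), dim = rep(64, 3)))
  v <- volume_grid(arr, diag(4))
  p <- resize_to_cube(v, edge = 64L)
  expect_identical(p$data, arr)
  expect_equal(p$scale_factor, 1)
  expect_equal(p$pad_offsets, rep(0L, 3))

  # 100 x 200 x 100 voxels at 1 mm: content 64 x 128 x 64, pads (32, 0, 32)
  v2 <- volume_grid(array(1, dim = c(100, 200, 100)), diag(4))
  p2 <- resize_to_cube(v2, edge = 128L)
  expect_equal(p2$scale_factor, 200 / 128)
  expect_equal(p2$content_dims, c(64L, 128L, 64L))
  expect_equal(p2$pad_offsets, c(32L, 0L, 32L))
  # aspect ratio of content extents matches physical extents within 1%
  expect_equal(p2$content_dims[1] / p2$content_dims[2],
               100 / 200, tolerance = 0.01)

  # marked-voxel round trip: cube -> world -> cube recovers the index
  v3 <- make_test_volume(dims = c(40L, 60L, 50L), spacing = c(1, 1, 1.5))
  p3 <- resize_to_cube(reorient_to_ras(v3), edge = 48L)
  pts <- rbind(c(10, 20, 30), c(4.5, 47, 1), c(0, 0, 0))
  back <- world_to_cube(p3, cube_to_world(p3, pts))
  expect_lt(max(abs(back - pts)), 0.5)
  # and the source-voxel mapping inverts exactly
  expect_equal(source_voxel_to_cube(p3, cube_to_source_voxel(p3, pts)), pts)
})

test_that("intensity standardization is content-driven and affine-invariant", {
  v <- make_test_volume(dims = c(30L, 50L, 30L), seed = 11L)
  p <- resize_to_cube(reorient_to_ras(v), edge = 48L)
  idx <- lapply(1:3, function(ax) {
    seq.int(p$pad_offsets[ax] + 1L, p$pad_offsets[ax] + p$content_dims[ax])
  })
  s <- standardize_intensity(p)
  region <- s$data[idx[[1]], idx[[2]], idx[[3]]]
  expect_equal(mean(region), 0, tolerance = 1e-8)
  expect_equal(stats::sd(as.vector(region)), 1, tolerance = 1e-8)

  # known moments: (x - mean) / sd over the statistics region
  mu <- mean(p$data[idx[[1]], idx[[2]], idx[[3]]])
  sigma <- stats::sd(as.vector(p$data[idx[[1]], idx[[2]], idx[[3]]]))
  expect_equal(s$data, (p$data - mu) / sigma)

  # affine invariance: a * x + b standardizes to the same volume
  p2 <- p
  p2$data <- 3.5 * p$data - 40
  s2 <- standardize_intensity(p2)
  expect_equal(s2$data, s$data, tolerance = 1e-10)

  # already standardized input comes back unchanged
  s3 <- standardize_intensity(s)
  expect_equal(s3$data, s$data, tolerance = 1e-10)

  # constant image errors
  pc <- p
  pc$data <- array(2, dim = dim(p$data))
  expect_error(standardize_intensity(pc), "constant")
})
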