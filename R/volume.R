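# NIfTI volume input/output and the preprocessing chain: RAS reorientation,
# aspect-preserving resize to an isotropic cube, intensity standardization.
# Voxel indices are 0-based throughout and index the *center* of a voxel;
# world coordinates are millimetres in RAS+.

#' Construct a volume grid
#'
#' A `volume_grid` couples a 3D intensity array with the 4x4 affine that maps
#' 0-based voxel indices to world (RAS, mm) coordinates.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return An object of class `volume_grid` with fields `data`, `affine`,
#'   `axis_codes` (orientation triple such as `c("R","A","S")`).
#' @export
volume_grid <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) {
    stop("non-3D volume: expected a 3D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  }
  if (any(dim(data) <= 0L)) stop("volume has an empty dimension", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  }
  structure(
    list(data = data, affine = affine, axis_codes = affine_axis_codes(affine)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, orientation ", paste(x$axis_codes, collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file (optionally gzip-compressed) and returns the
#' stored array and affine untouched (no resampling, no reorientation).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
load_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("missing file: ", path, call. = FALSE)
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop("unreadable NIfTI header/data in '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  arr <- as.array(img)
  d <- dim(arr)
  # trailing singleton dims (e.g. 3D stored as X x Y x Z x 1) are tolerated
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L) {
    stop("non-3D volume: '", path, "' has ", length(d), " dimensions",
         call. = FALSE)
  }
  volume_grid(arr, structure(RNifti::xform(img), imagedim = NULL, code = NULL))
}

#' Write a volume grid to NIfTI
#'
#' @param v a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- sqrt(colSums(v$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Orientation codes ("R"/"L", "A"/"P", "S"/"I") of the three voxel axes,
# from the dominant world component of each affine column.
affine_axis_codes <- function(affine) {
  m <- affine[1:3, 1:3]
  codes <- character(3)
  labs <- rbind(c("R", "A", "S"), c("L", "P", "I"))
  for (j in 1:3) {
    col <- m[, j]
    i <- which.max(abs(col))
    codes[j] <- if (col[i] >= 0) labs[1, i] else labs[2, i]
  }
  codes
}

#' Reorient a volume to RAS
#'
#' Permutes and flips the voxel axes so that they run Right, Anterior,
#' Superior, updating the affine so every voxel keeps its world position.
#' The intensity multiset is untouched; the operation is idempotent.
#'
#' @param v a [volume_grid()].
#' @return A [volume_grid()] with `axis_codes == c("R","A","S")`.
#' @export
reorient_to_ras <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  m <- v$affine[1:3, 1:3]
  perm <- integer(3)
  flip <- logical(3)
  for (world in 1:3) {
    contrib <- abs(m[world, ]) / sqrt(colSums(m^2))
    j <- which.max(contrib)
    if (contrib[j] < cos(pi / 4)) {
      stop("oblique affine: no voxel axis within 45 degrees of the ",
           c("R", "A", "S")[world],
           " axis; resample the volume explicitly before reorienting",
           call. = FALSE)
    }
    perm[world] <- j
    flip[world] <- m[world, j] < 0
  }
  if (anyDuplicated(perm)) {
    stop("oblique affine: ambiguous axis correspondence; resample explicitly",
         call. = FALSE)
  }
  if (identical(perm, 1:3) && !any(flip)) {
    v$axis_codes <- affine_axis_codes(v$affine)
    return(v)
  }
  data <- aperm(v$data, perm)
  dims <- dim(data)
  affine <- v$affine[, c(perm, 4)]
  for (ax in 1:3) {
    if (flip[ax]) {
      idx <- rev(seq_len(dims[ax]))
      data <- switch(ax,
        data[idx, , , drop = FALSE],
        data[, idx, , drop = FALSE],
        data[, , idx, drop = FALSE]
      )
      affine[1:3, 4] <- affine[1:3, 4] + affine[1:3, ax] * (dims[ax] - 1)
      affine[1:3, ax] <- -affine[1:3, ax]
    }
  }
  volume_grid(data, affine)
}

#' Resize a RAS volume into an isotropic cube
#'
#' Resamples the volume into an `edge`^3 cube with trilinear interpolation,
#' preserving the aspect ratio: the largest physical extent maps onto `edge`
#' voxels and the remaining axes are symmetrically padded with the volume's
#' minimum intensity (background proxy). The scale factor (mm per cube voxel)
#' and pad offsets are recorded so cube coordinates map back to source world
#' millimetres exactly.
#'
#' @param v a RAS-oriented [volume_grid()].
#' @param edge cube edge length in voxels (default 128).
#' @return An object of class `preprocessed_volume` with fields `data`
#'   (`edge`^3 array), `scale_factor` (mm per cube voxel), `pad_offsets`,
#'   `content_dims`, `source_affine`, `source_spacing`, `edge`,
#'   `standardized`.
#' @export
resize_to_cube <- function(v, edge = 128L) {
  stopifnot(inherits(v, "volume_grid"))
  if (!identical(v$axis_codes, c("R", "A", "S"))) {
    stop("resize_to_cube expects a RAS-oriented volume; ",
         "call reorient_to_ras() first", call. = FALSE)
  }
  edge <- as.integer(edge)
  dims <- dim(v$data)
  spacing <- sqrt(colSums(v$affine[1:3, 1:3]^2))
  extents <- dims * spacing
  if (any(extents <= 0)) stop("degenerate zero-extent axis", call. = FALSE)
  scale_factor <- max(extents) / edge
  content <- pmin(edge, pmax(1L, as.integer(round(extents / scale_factor))))
  pad <- (edge - content) %/% 2L
  background <- min(v$data)

  # Source fractional voxel index sampled by cube voxel c (0-based, centers):
  #   src = ((c - pad + 0.5) * scale_factor) / spacing - 0.5
  src_idx <- lapply(1:3, function(ax) {
    ((seq_len(edge) - 1 - pad[ax] + 0.5) * scale_factor) / spacing[ax] - 0.5
  })

  identity_map <- identical(content, dims) && all(pad == 0L) &&
    all(vapply(1:3, function(ax) {
      max(abs(src_idx[[ax]] - (seq_len(edge) - 1))) < 1e-9
    }, logical(1)))
  if (identity_map) {
    cube <- v$data
  } else {
    pts <- as.matrix(expand.grid(src_idx[[1]], src_idx[[2]], src_idx[[3]]))
    vals <- trilinear_sample(v$data, pts, background = background)
    cube <- array(vals, dim = rep(edge, 3))
  }
  structure(
    list(
      data = cube,
      scale_factor = scale_factor,
      pad_offsets = pad,
      content_dims = content,
      source_affine = v$affine,
      source_spacing = spacing,
      edge = edge,
      standardized = FALSE
    ),
    class = "preprocessed_volume"
  )
}

#' @export
print.preprocessed_volume <- function(x, ...) {
  cat("<preprocessed_volume> ", x$edge, "^3, scale_factor ",
      signif(x$scale_factor, 4), " mm/voxel, pads (",
      paste(x$pad_offsets, collapse = ", "), ")",
      if (isTRUE(x$standardized)) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

#' Standardize cube intensities
#'
#' Applies a per-volume standard scaler: subtracts the mean and divides by
#' the standard deviation computed over the non-padded content box, so that
#' padding does not bias the moments. The whole cube (padding included) is
#' transformed by the same affine map.
#'
#' @param p a `preprocessed_volume` from [resize_to_cube()].
#' @return The standardized `preprocessed_volume`; `$intensity_stats` records
#'   the moments used.
#' @export
standardize_intensity <- function(p) {
  stopifnot(inherits(p, "preprocessed_volume"))
  idx <- lapply(1:3, function(ax) {
    seq.int(p$pad_offsets[ax] + 1L, p$pad_offsets[ax] + p$content_dims[ax])
  })
  region <- p$data[idx[[1]], idx[[2]], idx[[3]]]
  mu <- mean(region)
  sigma <- stats::sd(as.vector(region))
  if (!is.finite(sigma) || sigma < .Machine$double.eps^0.5) {
    stop("constant image: intensity standard deviation is zero", call. = FALSE)
  }
  p$data <- (p$data - mu) / sigma
  p$standardized <- TRUE
  p$intensity_stats <- c(mean = mu, sd = sigma)
  p
}

#' Preprocess a volume for callosal-angle measurement
#'
#' Convenience chain: [reorient_to_ras()], [resize_to_cube()],
#' [standardize_intensity()].
#'
#' @param v a [volume_grid()].
#' @param edge cube edge (default 128).
#' @param standardize standardize intensities (default `TRUE`).
#' @return A `preprocessed_volume`.
#' @export
preprocess_volume <- function(v, edge = 128L, standardize = TRUE) {
  p <- resize_to_cube(reorient_to_ras(v), edge = edge)
  if (standardize) p <- standardize_intensity(p) else p
}

# ---- coordinate transforms between cube voxels, source voxels and world ----

#' Map cube voxel coordinates to source voxel coordinates
#'
#' @param p a `preprocessed_volume`.
#' @param pts numeric 3-vector or n x 3 matrix of 0-based cube coordinates.
#' @return Matching source voxel coordinates (0-based, fractional).
#' @export
cube_to_source_voxel <- function(p, pts) {
  m <- if (is.matrix(pts)) pts else matrix(pts, nrow = 1)
  out <- m
  for (ax in 1:3) {
    out[, ax] <- ((m[, ax] - p$pad_offsets[ax] + 0.5) * p$scale_factor) /
      p$source_spacing[ax] - 0.5
  }
  if (is.matrix(pts)) out else drop(out)
}

#' Map source voxel coordinates to cube voxel coordinates
#' @rdname cube_to_source_voxel
#' @export
source_voxel_to_cube <- function(p, pts) {
  m <- if (is.matrix(pts)) pts else matrix(pts, nrow = 1)
  out <- m
  for (ax in 1:3) {
    out[, ax] <- ((m[, ax] + 0.5) * p$source_spacing[ax]) / p$scale_factor +
      p$pad_offsets[ax] - 0.5
  }
  if (is.matrix(pts)) out else drop(out)
}

#' Map cube voxel coordinates to world millimetres (RAS)
#' @rdname cube_to_source_voxel
#' @export
cube_to_world <- function(p, pts) {
  src <- cube_to_source_voxel(p, pts)
  m <- if (is.matrix(src)) src else matrix(src, nrow = 1)
  w <- t(p$source_affine %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (is.matrix(pts)) w else drop(w)
}

#' Map world millimetres (RAS) to cube voxel coordinates
#' @rdname cube_to_source_voxel
#' @export
world_to_cube <- function(p, pts) {
  m <- if (is.matrix(pts)) pts else matrix(pts, nrow = 1)
  src <- t(solve(p$source_affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  source_voxel_to_cube(p, if (is.matrix(pts)) src else drop(src))
}
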