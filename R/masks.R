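# 2D multiclass ventricle masks (0 background, 1 left ventricle, 2 right
# ventricle), subpixel boundary contours, segmentation metrics (Dice,
# Hausdorff) and the segmenter provider contract replacing the trained UNet.
#
# "Left ventricle" means the anatomical left; with the plane frame of
# build_plane() (columns increase toward the subject's right) the left
# ventricle occupies the lower column indices of the slice.

#' Construct a ventricle mask
#'
#' @param labels integer matrix with values in \{0, 1, 2\}
#'   (background / left ventricle / right ventricle), rows increasing
#'   inferiorly like [slice_2d()].
#' @param spacing pixel pitch (mm or cube voxels) used to scale distance
#'   metrics; default 1.
#' @return An object of class `ventricle_mask`.
#' @export
ventricle_mask <- function(labels, spacing = 1) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(round(labels)), nrow = nrow(labels))
  if (!all(labels %in% 0:2)) {
    stop("mask labels must be 0 (background), 1 (left) or 2 (right)",
         call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing),
            class = "ventricle_mask")
}

#' @export
print.ventricle_mask <- function(x, ...) {
  cat("<ventricle_mask> ", nrow(x$labels), " x ", ncol(x$labels),
      " px; left ", sum(x$labels == 1L), " px, right ",
      sum(x$labels == 2L), " px\n", sep = "")
  invisible(x)
}

class_name <- function(class_id) c("left", "right")[class_id]

#' Extract the boundary contour of each ventricle
#'
#' Traces the closed boundary of the largest connected region of each class
#' at the 0.5 iso-level between class and non-class pixels (marching-squares
#' style, subpixel vertices). Contour points are (x = column, y = row),
#' 0-based.
#'
#' @param m a [ventricle_mask()].
#' @param min_px smallest acceptable region size in pixels (default 5).
#' @return A list with elements `left` and `right`, each of class
#'   `ventricle_contour`: `points` (n x 2), `class_id`, `closed`.
#' @export
extract_contours <- function(m, min_px = 5L) {
  stopifnot(inherits(m, "ventricle_mask"))
  list(left = class_contour(m$labels, 1L, min_px),
       right = class_contour(m$labels, 2L, min_px))
}

class_contour <- function(labels, class_id, min_px = 5L) {
  ind <- labels == class_id
  npx <- sum(ind)
  if (npx == 0L) {
    stop("missing class: no '", class_name(class_id),
         "' ventricle pixels in the mask", call. = FALSE)
  }
  if (npx < min_px) {
    warning("'", class_name(class_id), "' ventricle has only ", npx,
            " px (< ", min_px, ")", call. = FALSE)
    stop("'", class_name(class_id), "' ventricle region too small (", npx,
         " px)", call. = FALSE)
  }
  # zero-pad so regions touching the border still yield closed loops
  z <- matrix(0, nrow(labels) + 2L, ncol(labels) + 2L)
  z[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)] <- ind * 1
  # contourLines: its `x` runs over rows of z (our y), `y` over columns (x)
  cl <- grDevices::contourLines(
    x = seq_len(nrow(z)) - 2,  # row coordinate, 0-based after unpadding
    y = seq_len(ncol(z)) - 2,
    z = z, levels = 0.5
  )
  if (length(cl) == 0L) {
    stop("no boundary found for class '", class_name(class_id), "'",
         call. = FALSE)
  }
  areas <- vapply(cl, function(cc) {
    abs(shoelace_area(cbind(cc$y, cc$x)))
  }, numeric(1))
  best <- cl[[which.max(areas)]]
  pts <- cbind(x = best$y, y = best$x)
  # drop a duplicated closing vertex if present; closure is implicit
  if (nrow(pts) > 1L && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9)) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3L) stop("degenerate contour for class '",
                           class_name(class_id), "'", call. = FALSE)
  structure(list(points = pts, class_id = class_id, closed = TRUE),
            class = "ventricle_contour")
}

#' @export
print.ventricle_contour <- function(x, ...) {
  cat("<ventricle_contour> class ", x$class_id, " (",
      class_name(x$class_id), "), ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

contour_polygon <- function(contour) {
  pts <- contour$points
  rbind(pts, pts[1, ])
}

#' Dice similarity coefficient
#'
#' Per-class Dice `2|A n B| / (|A| + |B|)` and their mean. A class empty in
#' both masks scores 1, empty in exactly one scores 0 (the formula is 0/0
#' there).
#'
#' @param a,b [ventricle_mask()] objects of identical shape.
#' @return A list with `per_class` (named numeric, left/right) and `mean`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "ventricle_mask"), inherits(b, "ventricle_mask"))
  if (!all(dim(a$labels) == dim(b$labels))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  per_class <- vapply(1:2, function(cls) {
    na <- sum(a$labels == cls); nb <- sum(b$labels == cls)
    if (na + nb == 0L) return(1)
    2 * sum(a$labels == cls & b$labels == cls) / (na + nb)
  }, numeric(1))
  names(per_class) <- c("left", "right")
  list(per_class = per_class, mean = mean(per_class))
}

#' Symmetric Hausdorff distance between two point sets
#'
#' `max(sup_a inf_b ||a - b||, sup_b inf_a ||a - b||)`, scaled by `spacing`.
#' Accepts contours or raw n x 2 matrices; for closed regions this is the
#' boundary Hausdorff distance.
#'
#' @param a,b `ventricle_contour` objects or n x 2 point matrices.
#' @param spacing scalar multiplier applied to the result (mm per pixel);
#'   default 1.
#' @return Scalar distance.
#' @export
hausdorff_distance <- function(a, b, spacing = 1) {
  pa <- if (inherits(a, "ventricle_contour")) a$points else as.matrix(a)
  pb <- if (inherits(b, "ventricle_contour")) b$points else as.matrix(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("Hausdorff distance of an empty set is undefined", call. = FALSE)
  }
  d <- cross_distances(pa, pb)
  max(max(apply(d, 1, min)), max(apply(d, 2, min))) * spacing
}

#' Mean segmentation metrics over a cohort
#'
#' Mean Dice similarity coefficient and mean (boundary) Hausdorff distance
#' over paired lists of predicted and reference masks.
#'
#' @param pred,truth lists of [ventricle_mask()] objects (paired).
#' @return A tibble with one row per case and class plus columns `dice` and
#'   `hausdorff`; aggregate means are in `attr(, "summary")`.
#' @export
segmentation_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  rows <- purrr::map_dfr(seq_along(pred), function(i) {
    dc <- dice_coefficient(pred[[i]], truth[[i]])
    hd <- vapply(1:2, function(cls) {
      pa <- tryCatch(class_contour(pred[[i]]$labels, cls),
                     error = function(e) NULL)
      pb <- tryCatch(class_contour(truth[[i]]$labels, cls),
                     error = function(e) NULL)
      if (is.null(pa) || is.null(pb)) return(NA_real_)
      hausdorff_distance(pa, pb, spacing = truth[[i]]$spacing)
    }, numeric(1))
    tibble::tibble(case = i, class = c("left", "right"),
                   dice = unname(dc$per_class), hausdorff = hd)
  })
  attr(rows, "summary") <- c(mdsc = mean(rows$dice),
                             mhd = mean(rows$hausdorff, na.rm = TRUE))
  rows
}

# ---- mask file I/O ---------------------------------------------------------

#' Read / write ventricle masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with pixel values equal to the
#' class labels (0/1/2 out of 255).
#'
#' @param path PNG file path.
#' @param spacing pixel pitch recorded on the mask (default 1).
#' @return `read_mask_png()` a [ventricle_mask()]; `write_mask_png()` the
#'   path, invisibly.
#' @export
read_mask_png <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("missing mask file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  ventricle_mask(round(img * 255), spacing = spacing)
}

#' @param m a [ventricle_mask()].
#' @rdname read_mask_png
#' @export
write_mask_png <- function(m, path) {
  stopifnot(inherits(m, "ventricle_mask"))
  png::writePNG(m$labels / 255, path)
  invisible(path)
}

# ---- segmenter providers ---------------------------------------------------

#' Segmenter providers
#'
#' A segmenter is a deterministic function
#' `function(slice, pre) -> ventricle_mask` standing in for the trained
#' ventricle-segmentation network. `file_segmenter()` reads a mask image
#' that must match the slice shape; `phantom_segmenter()` rasterizes the
#' analytic ventricle solids of a phantom on the slice's own pixel grid
#' (see [make_phantom_volume()]).
#'
#' @param path mask file (PNG, see [read_mask_png()]).
#' @return A function `(slice_2d, preprocessed_volume) -> ventricle_mask`.
#' @export
file_segmenter <- function(path) {
  force(path)
  function(slice, pre = NULL) {
    m <- read_mask_png(path)
    if (!all(dim(m$labels) == dim(slice$data))) {
      stop("mask shape ", paste(dim(m$labels), collapse = "x"),
           " does not match slice shape ",
           paste(dim(slice$data), collapse = "x"), call. = FALSE)
    }
    m$spacing <- slice$plane$spacing
    m
  }
}

#' Mirror a mask left-right
#'
#' Reverses the column order and swaps the left/right class labels, i.e.
#' the anatomical mirror image. Used by symmetry tests.
#'
#' @param m a [ventricle_mask()].
#' @return The mirrored [ventricle_mask()].
#' @export
mirror_mask <- function(m) {
  stopifnot(inherits(m, "ventricle_mask"))
  flipped <- m$labels[, rev(seq_len(ncol(m$labels))), drop = FALSE]
  swapped <- flipped
  swapped[flipped == 1L] <- 2L
  swapped[flipped == 2L] <- 1L
  ventricle_mask(swapped, spacing = m$spacing)
}
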