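# AC/PC landmarks, landmark providers (file-based and phantom), and the
# landmark-evaluation metrics: Euclidean error, PCK@10, pitch angle.

#' Construct an AC/PC landmark set
#'
#' Holds the anterior and posterior commissure positions in both cube-voxel
#' coordinates (0-based, RAS cube) and world millimetres (RAS).
#'
#' @param ac,pc 3-vectors, cube voxel coordinates.
#' @param world_ac,world_pc 3-vectors, world mm (RAS). If omitted and `pre`
#'   is given they are derived via [cube_to_world()]; otherwise they default
#'   to the cube coordinates (unit spacing).
#' @param source one of `"annotated"`, `"predicted"`, `"phantom"`.
#' @param pre optional `preprocessed_volume` used to derive world coords.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(ac, pc, world_ac = NULL, world_pc = NULL,
                         source = c("annotated", "predicted", "phantom"),
                         pre = NULL) {
  source <- match.arg(source)
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  stopifnot(length(ac) == 3L, length(pc) == 3L)
  if (!all(is.finite(c(ac, pc)))) stop("non-finite landmark coordinates",
                                       call. = FALSE)
  if (sqrt(sum((ac - pc)^2)) < 1e-9) {
    stop("degenerate landmarks: AC equals PC", call. = FALSE)
  }
  if (is.null(world_ac)) {
    world_ac <- if (!is.null(pre)) cube_to_world(pre, ac) else ac
  }
  if (is.null(world_pc)) {
    world_pc <- if (!is.null(pre)) cube_to_world(pre, pc) else pc
  }
  structure(
    list(ac = ac, pc = pc, world_ac = as.numeric(world_ac),
         world_pc = as.numeric(world_pc), source = source),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (", x$source, ")\n  AC cube (",
      paste(signif(x$ac, 5), collapse = ", "), ") world (",
      paste(signif(x$world_ac, 5), collapse = ", "), ") mm\n  PC cube (",
      paste(signif(x$pc, 5), collapse = ", "), ") world (",
      paste(signif(x$world_pc, 5), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Read landmarks from a JSON file
#'
#' Expects `{"ac": [x,y,z], "pc": [x,y,z], "space": "voxel"|"world"}`.
#' `"voxel"` coordinates are source-volume voxel indices (0-based) and are
#' converted to cube/world coordinates through `pre`; `"world"` coordinates
#' are RAS millimetres.
#'
#' @param path JSON file path.
#' @param pre `preprocessed_volume` defining the coordinate mapping.
#' @param source provenance tag, default `"annotated"`.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, pre, source = "annotated") {
  if (!file.exists(path)) stop("missing landmark file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$ac) || is.null(j$pc)) {
    stop("landmark file must contain 'ac' and 'pc'", call. = FALSE)
  }
  space <- if (is.null(j$space)) "voxel" else j$space
  ac <- as.numeric(j$ac); pc <- as.numeric(j$pc)
  if (identical(space, "voxel")) {
    landmark_set(ac = source_voxel_to_cube(pre, ac),
                 pc = source_voxel_to_cube(pre, pc),
                 source = source, pre = pre)
  } else if (identical(space, "world")) {
    landmark_set(ac = world_to_cube(pre, ac), pc = world_to_cube(pre, pc),
                 world_ac = ac, world_pc = pc, source = source)
  } else {
    stop("unknown landmark space '", space, "'", call. = FALSE)
  }
}

#' Write landmarks to JSON
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @param space `"world"` (default) or `"voxel"` (requires `pre`).
#' @param pre `preprocessed_volume`, needed for `"voxel"` output.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, space = c("world", "voxel"),
                            pre = NULL) {
  space <- match.arg(space)
  obj <- if (space == "world") {
    list(ac = lm$world_ac, pc = lm$world_pc, space = "world")
  } else {
    stopifnot(!is.null(pre))
    list(ac = cube_to_source_voxel(pre, lm$ac),
         pc = cube_to_source_voxel(pre, lm$pc), space = "voxel")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Landmark providers
#'
#' A landmark provider is a deterministic function
#' `function(pre) -> landmark_set` replacing the trained landmark-detection
#' network. `file_landmark_provider()` reads a JSON file;
#' `phantom_landmark_provider()` serves the analytic truth of a phantom.
#'
#' @param path JSON landmark file (see [read_landmarks()]).
#' @return A function of a `preprocessed_volume` returning a
#'   [landmark_set()].
#' @export
file_landmark_provider <- function(path) {
  force(path)
  function(pre) read_landmarks(path, pre, source = "annotated")
}

#' @param truth a `landmark_set`-like list with `world_ac`/`world_pc` (as
#'   produced by [make_phantom_volume()]).
#' @rdname file_landmark_provider
#' @export
phantom_landmark_provider <- function(truth) {
  force(truth)
  function(pre) {
    landmark_set(ac = world_to_cube(pre, truth$world_ac),
                 pc = world_to_cube(pre, truth$world_pc),
                 world_ac = truth$world_ac, world_pc = truth$world_pc,
                 source = "phantom")
  }
}

#' Euclidean landmark error
#'
#' 3D Euclidean distance between predicted and reference AC and PC, in the
#' world frame (millimetres when source spacing is known).
#'
#' @param pred,truth [landmark_set()] objects in the same frame.
#' @return Named numeric vector `c(ac = ..., pc = ...)`.
#' @export
landmark_error <- function(pred, truth) {
  stopifnot(inherits(pred, "landmark_set"), inherits(truth, "landmark_set"))
  c(ac = vnorm(pred$world_ac - truth$world_ac),
    pc = vnorm(pred$world_pc - truth$world_pc))
}

#' Percentage of correct keypoints at 10% (PCK@10)
#'
#' A landmark is correct iff its Euclidean error is strictly less than 10%
#' of the reference AC-PC distance. With lists of landmark sets the
#' aggregate fraction of correct landmarks over the cohort is also returned.
#'
#' @param pred,truth [landmark_set()] objects, or lists thereof (paired).
#' @param fraction correctness threshold as a fraction of the AC-PC
#'   distance (default 0.10).
#' @return A list with `correct` (logical matrix, columns ac/pc) and
#'   `pck` (aggregate fraction in \[0, 1\]).
#' @export
pck_at_10 <- function(pred, truth, fraction = 0.10) {
  if (inherits(pred, "landmark_set")) pred <- list(pred)
  if (inherits(truth, "landmark_set")) truth <- list(truth)
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  correct <- t(vapply(seq_along(pred), function(i) {
    d_acpc <- vnorm(truth[[i]]$world_ac - truth[[i]]$world_pc)
    if (d_acpc < 1e-12) stop("zero AC-PC distance in reference set ", i,
                             call. = FALSE)
    landmark_error(pred[[i]], truth[[i]]) < fraction * d_acpc
  }, logical(2)))
  colnames(correct) <- c("ac", "pc")
  list(correct = correct, pck = mean(correct))
}

#' Pitch angle between two AC-PC lines
#'
#' Undirected 3D angle between the AC-PC directions of two landmark sets,
#' in degrees, range \[0, 90\]. Used as the pitch-correction error metric
#' when comparing predicted to annotated landmarks.
#'
#' @param l1,l2 [landmark_set()] objects.
#' @return Angle in degrees.
#' @export
pitch_angle_between <- function(l1, l2) {
  d1 <- unit(l1$world_ac - l1$world_pc)
  d2 <- unit(l2$world_ac - l2$world_pc)
  rad2deg(acos(clamp(abs(sum(d1 * d2)), 0, 1)))
}
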