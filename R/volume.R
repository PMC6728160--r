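#' Cardiac MR volume container
#'
#' A 3D scalar intensity grid with anisotropic voxel spacing and world-affine
#' metadata. Voxel indices are 0-based; the world (mm) coordinate of voxel
#' index `v` is `origin + axes %*% (spacing * v)`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param axes 3x3 direction-cosine matrix (columns are the world directions of
#'   the voxel axes).
#' @return An object of class `cmr_volume`.
#' @export
cmr_volume <- function(data, spacing = c(1.25, 1.25, 2), origin = c(0, 0, 0),
                       axes = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (any(dim(data) < 1L)) stop("grid dimensions must each be >= 1")
  if (!all(is.finite(data))) stop("'data' must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) stop("invalid 'origin'")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3L, 3L)) || abs(det(axes)) < 1e-8)
    stop("'axes' must be an invertible 3x3 matrix")
  structure(list(data = data, spacing = spacing, origin = origin, axes = axes),
            class = "cmr_volume")
}

#' Label map container
#'
#' An integer grid on the same lattice convention as [cmr_volume()], with
#' values in `0 .. n_classes - 1`. The default 5 classes encode background (0),
#' left ventricular cavity LVC (1), left ventricular wall LVW (2), right
#' ventricular cavity RVC (3) and right ventricular wall RVW (4).
#'
#' @inheritParams cmr_volume
#' @param n_classes number of label classes including background.
#' @return An object of class `cmr_labelmap`.
#' @export
cmr_labelmap <- function(data, spacing = c(1.25, 1.25, 2), origin = c(0, 0, 0),
                         axes = diag(3), n_classes = 5L) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "integer"
  n_classes <- as.integer(n_classes)
  if (anyNA(data) || any(data < 0L) || any(data >= n_classes))
    stop(sprintf("label values must lie in [0, %d)", n_classes))
  obj <- cmr_volume(array(0, dim(data)), spacing, origin, axes)
  obj$data <- data
  obj$n_classes <- n_classes
  class(obj) <- c("cmr_labelmap", "cmr_volume")
  obj
}

#' Segmentation class codes
#'
#' Named integer codes of the 4 foreground tissue classes plus background.
#' @export
seg_classes <- function() {
  c(background = 0L, LVC = 1L, LVW = 2L, RVC = 3L, RVW = 4L)
}

#' Landmark names and anatomical meaning
#'
#' The six anatomical landmarks used to initialise atlas propagation:
#' I and III are the two right-ventricular insert points, II the
#' right-ventricular lateral-wall turning point, IV the left-ventricular
#' lateral-wall mid-point, V the apex and VI the centre of the mitral valve.
#' @return character vector of the six landmark names.
#' @export
landmark_names <- function() c("I", "II", "III", "IV", "V", "VI")

#' Landmark set container
#'
#' Up to six named 3D landmarks, stored both as 0-based voxel indices and as
#' world coordinates in mm. A set is *complete* when all six landmarks are
#' present.
#'
#' @param voxel integer matrix (n x 3) of 0-based voxel indices with rownames
#'   from [landmark_names()].
#' @param world numeric matrix (n x 3) of world coordinates (mm). If `NULL`,
#'   computed from `voxel` and the reference grid `ref`.
#' @param ref optional [cmr_volume()] supplying the lattice for voxel/world
#'   conversion checks.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(voxel, world = NULL, ref = NULL) {
  voxel <- as.matrix(voxel)
  if (ncol(voxel) != 3L) stop("'voxel' must have 3 columns")
  if (nrow(voxel) == 0L) {
    storage.mode(voxel) <- "integer"
    world <- matrix(numeric(), 0L, 3L)
    return(structure(list(voxel = voxel, world = world), class = "landmark_set"))
  }
  if (is.null(rownames(voxel)) || !all(rownames(voxel) %in% landmark_names()))
    stop("landmark rownames must be among ", paste(landmark_names(), collapse = ", "))
  if (anyDuplicated(rownames(voxel))) stop("duplicate landmark names")
  storage.mode(voxel) <- "integer"
  if (is.null(world)) {
    if (is.null(ref)) stop("'ref' needed to derive world coordinates")
    world <- vox2world(ref, voxel)
  }
  world <- as.matrix(world)
  rownames(world) <- rownames(voxel)
  if (!is.null(ref)) {
    d <- dim(ref$data)
    if (any(voxel < 0L) || any(t(voxel) >= d))
      stop("landmark voxel indices fall outside the grid")
  }
  structure(list(voxel = voxel, world = world), class = "landmark_set")
}

#' @export
print.cmr_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s)\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d of 6 landmarks: %s\n", nrow(x$voxel),
              paste(rownames(x$voxel), collapse = " ")))
  invisible(x)
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param obj a [cmr_volume()] or [cmr_labelmap()].
#' @param idx numeric matrix (n x 3) or length-3 vector of 0-based indices
#'   (fractional indices allowed).
#' @return numeric matrix (n x 3) of world coordinates.
#' @export
vox2world <- function(obj, idx) {
  idx <- if (is.matrix(idx)) idx else matrix(idx, ncol = 3L)
  sweep(t(obj$axes %*% (t(idx) * obj$spacing)), 2L, obj$origin, "+")
}

#' Convert world coordinates (mm) to 0-based (fractional) voxel indices
#'
#' @inheritParams vox2world
#' @param world numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return numeric matrix (n x 3) of fractional voxel indices.
#' @export
world2vox <- function(obj, world) {
  world <- if (is.matrix(world)) world else matrix(world, ncol = 3L)
  t(solve(obj$axes, t(sweep(world, 2L, obj$origin, "-")))) %*% diag(1 / obj$spacing)
}

#' Is a landmark set complete?
#' @param lm a [landmark_set()].
#' @return `TRUE` when all six landmarks are present.
#' @export
is_complete <- function(lm) {
  inherits(lm, "landmark_set") && all(landmark_names() %in% rownames(lm$voxel))
}

# lattice equality check used by operations requiring a shared grid
same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$axes - b$axes)) < tol
}

assert_same_lattice <- function(a, b, what = "inputs") {
  if (!same_lattice(a, b))
    stop_bivseg(sprintf("%s must share the same lattice", what), "bivseg_shape_error")
  invisible(TRUE)
}
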