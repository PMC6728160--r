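#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a [cmr_volume()]. Spacing, origin and direction
#' cosines are recovered from the image xform.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [cmr_volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_bivseg(
                    sprintf("cannot read NIfTI file '%s': %s", path, conditionMessage(e)),
                    "bivseg_format_error"))
  dd <- dim(img)
  if (length(dd) > 3L) dd <- dd[1:3]
  if (length(dd) < 3L) dd <- c(dd, rep(1L, 3L - length(dd)))
  dat <- array(as.numeric(img)[seq_len(prod(dd))], dd)
  A <- unclass(RNifti::xform(img))
  spacing <- RNifti::pixdim(img)[1:3]
  axes <- A[1:3, 1:3] %*% diag(1 / spacing)
  cmr_volume(dat, spacing = spacing, origin = A[1:3, 4], axes = axes)
}

#' Read a NIfTI label map
#'
#' @inheritParams read_volume
#' @param n_classes number of classes expected (default 5).
#' @return A [cmr_labelmap()].
#' @export
read_labelmap <- function(path, n_classes = 5L) {
  v <- read_volume(path)
  dat <- round(v$data)
  if (max(abs(dat - v$data)) > 1e-6)
    stop_bivseg(sprintf("'%s' does not contain integer labels", path),
                "bivseg_format_error")
  cmr_labelmap(dat, v$spacing, v$origin, v$axes, n_classes = n_classes)
}

nifti_affine <- function(v) {
  A <- diag(4)
  A[1:3, 1:3] <- v$axes %*% diag(v$spacing)
  A[1:3, 4] <- v$origin
  A
}

#' Write a volume or label map to NIfTI
#'
#' Volumes are stored as float64 (bit-exact round trip), label maps as int16.
#'
#' @param v a [cmr_volume()] or [cmr_labelmap()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "cmr_volume"))
  dt <- if (inherits(v, "cmr_labelmap")) "int16" else "double"
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(nifti_affine(v), code = 2L)
  RNifti::qform(img) <- structure(nifti_affine(v), code = 1L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_labelmap <- function(v, path) write_volume(v, path)

#' Read / write a landmark set as JSON
#'
#' The on-disk format is `{name: {voxel: [i,j,k], world_mm: [x,y,z]}, ...}`
#' with 0-based voxel indices.
#'
#' @param lm a [landmark_set()].
#' @param path JSON file path.
#' @return `read_landmarks` returns a [landmark_set()]; `write_landmarks`
#'   returns `path` invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  obj <- lapply(rownames(lm$voxel), function(nm) {
    list(voxel = as.integer(lm$voxel[nm, ]), world_mm = as.numeric(lm$world[nm, ]))
  })
  names(obj) <- rownames(lm$voxel)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_bivseg(
                    sprintf("cannot read landmark JSON '%s'", path),
                    "bivseg_format_error"))
  nms <- names(obj)
  voxel <- do.call(rbind, lapply(obj, function(e) as.integer(e$voxel)))
  world <- do.call(rbind, lapply(obj, function(e) as.numeric(e$world_mm)))
  rownames(voxel) <- rownames(world) <- nms
  landmark_set(voxel, world)
}
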