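#' Dice overlap index for one class
#'
#' `2|A n B| / (|A| + |B|)` for the binary masks of class `cls`; symmetric in
#' its arguments, 1 when both masks are empty and 0 when exactly one is.
#'
#' @param a,b [cmr_labelmap()] objects (or integer arrays) on the same
#'   lattice.
#' @param cls class code (see [seg_classes()]).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b, cls) {
  da <- if (inherits(a, "cmr_labelmap")) a$data else a
  db <- if (inherits(b, "cmr_labelmap")) b$data else b
  if (!identical(dim(da), dim(db)))
    stop_bivseg("label maps must share the same lattice", "bivseg_shape_error")
  ma <- da == cls
  mb <- db == cls
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' Hausdorff distance for one class (mm)
#'
#' Symmetric Hausdorff distance between the 26-connectivity boundary voxels
#' of the two class masks, with voxel centres mapped to mm through the
#' spacing. Undefined (an error condition, not 0) when either mask is empty.
#'
#' @inheritParams dice
#' @return distance in mm.
#' @export
hausdorff <- function(a, b, cls) {
  stopifnot(inherits(a, "cmr_labelmap"), inherits(b, "cmr_labelmap"))
  assert_same_lattice(a, b, "label maps")
  ma <- a$data == cls
  mb <- b$data == cls
  if (!any(ma) || !any(mb))
    stop_bivseg(sprintf("Hausdorff distance undefined: empty mask for class %s", cls),
                "bivseg_undefined_value")
  d <- dim(ma)
  ba <- cpp_boundary_mask(ma, d)
  bb <- cpp_boundary_mask(mb, d)
  # directed max-min distances via exact Euclidean distance transforms of the
  # boundary voxel sets
  da <- cpp_edt_sq(bb, d, a$spacing)
  db <- cpp_edt_sq(ba, d, a$spacing)
  sqrt(max(max(da[ba]), max(db[bb])))
}

#' Point-to-point landmark localisation error
#'
#' Euclidean distances in world mm between landmarks shared by name, with a
#' mean +/- sd summary and a cumulative error distribution (fraction of
#' landmarks below each threshold). Landmarks missing from `pred` are
#' reported absent and excluded from the summary.
#'
#' @param pred,truth [landmark_set()] objects.
#' @param thresholds threshold grid (mm) for the cumulative error
#'   distribution.
#' @return list with `per_landmark` (named distances, mm), `mean`, `sd`, `n`,
#'   `missing` (names), and `ced` (data.frame threshold/fraction).
#' @export
landmark_error <- function(pred, truth, thresholds = c(0:20, Inf)) {
  shared <- intersect(rownames(truth$world), rownames(pred$world))
  missing <- setdiff(rownames(truth$world), shared)
  d <- if (length(shared))
    sqrt(rowSums((pred$world[shared, , drop = FALSE] -
                    truth$world[shared, , drop = FALSE])^2))
  else numeric()
  names(d) <- shared
  ced <- data.frame(threshold = thresholds,
                    fraction = vapply(thresholds, function(th) {
                      if (length(d) == 0) return(NA_real_)
                      mean(d <= th)
                    }, 0))
  list(per_landmark = d,
       mean = if (length(d)) mean(d) else NA_real_,
       sd = if (length(d) > 1) sd(d) else NA_real_,
       n = length(d), missing = missing, ced = ced)
}

#' Ventricular volumes and masses from a segmentation
#'
#' Cavity volumes are voxel counts times the voxel volume (ml); myocardial
#' masses are wall volumes times the myocardial density (default 1.05 g/ml,
#' the standard CMR convention).
#'
#' @param seg a [cmr_labelmap()] with the standard class codes.
#' @param density myocardial density in g/ml.
#' @return list with `LVV` (ml), `LVM` (g), `RVV` (ml), `RVM` (g).
#' @export
clinical_measures <- function(seg, density = 1.05) {
  stopifnot(inherits(seg, "cmr_labelmap"))
  voxvol_ml <- prod(seg$spacing) / 1000
  counts <- tabulate(as.integer(seg$data) + 1L, nbins = 5L)
  list(LVV = counts[2] * voxvol_ml,
       LVM = counts[3] * voxvol_ml * density,
       RVV = counts[4] * voxvol_ml,
       RVM = counts[5] * voxvol_ml * density)
}

#' Per-class segmentation scores
#'
#' Dice and Hausdorff distance for each foreground class.
#'
#' @inheritParams dice
#' @param classes named class codes (default the 4 foreground tissues).
#' @param with_hausdorff set `FALSE` to skip the Hausdorff computation.
#' @return data.frame with columns class, dice, hausdorff_mm.
#' @export
seg_scores <- function(a, b, classes = seg_classes()[-1], with_hausdorff = TRUE) {
  data.frame(
    class = names(classes),
    dice = vapply(classes, function(k) dice(a, b, k), 0),
    hausdorff_mm = vapply(classes, function(k) {
      if (!with_hausdorff) return(NA_real_)
      tryCatch(hausdorff(a, b, k), error = function(e) NA_real_)
    }, 0),
    row.names = NULL)
}
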