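#' Low-resolution artefact simulation specification
#'
#' Parameters of the cardiac artefact simulator: slice-thickness reduction
#' (high-resolution stacks downsampled to thick slices), random in-plane
#' inter-slice shift emulating different breath-hold positions, and optional
#' loss of apical slice coverage.
#'
#' @param target_z_spacing thick-slice spacing in mm (default 10).
#' @param max_shift_mm maximum absolute in-plane shift per slice (mm).
#' @param apical_truncation_slices number of thick slices removed at the apex.
#' @param rng_seed integer seed for the shift draws.
#' @return An `artefact_spec` list.
#' @export
artefact_spec <- function(target_z_spacing = 10, max_shift_mm = 5,
                          apical_truncation_slices = 0L, rng_seed = 1L) {
  check_scalar_num(target_z_spacing, "target_z_spacing", positive = TRUE)
  if (max_shift_mm < 0) stop("'max_shift_mm' must be >= 0")
  if (apical_truncation_slices < 0) stop("'apical_truncation_slices' must be >= 0")
  structure(list(target_z_spacing = target_z_spacing, max_shift_mm = max_shift_mm,
                 apical_truncation_slices = as.integer(apical_truncation_slices),
                 rng_seed = as.integer(rng_seed)),
            class = "artefact_spec")
}

#' Reduce long-axis resolution to thick slices
#'
#' Groups of consecutive thin slices are collapsed into one thick slice:
#' intensities by mean pooling (approximating slice-profile averaging), labels
#' by majority vote (ties to the lower class). The in-plane grid is unchanged.
#' If the spacing ratio is not an integer the input is first resampled along z
#' to the nearest divisor.
#'
#' @param v a [cmr_volume()] or [cmr_labelmap()].
#' @param spec an [artefact_spec()].
#' @return Object of the same class with `target_z_spacing` slice thickness.
#' @export
thick_slice <- function(v, spec = artefact_spec()) {
  stopifnot(inherits(v, "cmr_volume"))
  if (spec$target_z_spacing < v$spacing[3] - 1e-9)
    stop("target z spacing must be >= source z spacing")
  ratio <- spec$target_z_spacing / v$spacing[3]
  if (abs(ratio - round(ratio)) > 1e-6) {
    div_spacing <- spec$target_z_spacing / max(1, round(ratio))
    v <- resample(v, c(v$spacing[1:2], div_spacing))
    ratio <- spec$target_z_spacing / v$spacing[3]
  }
  r <- as.integer(round(ratio))
  if (r == 1L) return(v)
  d <- dim(v$data)
  nz <- d[3] %/% r
  is_lab <- inherits(v, "cmr_labelmap")
  out <- array(if (is_lab) 0L else 0, c(d[1], d[2], nz))
  for (k in seq_len(nz)) {
    grp <- v$data[, , ((k - 1) * r + 1):(k * r), drop = FALSE]
    if (is_lab) {
      # per-voxel majority vote across the constituent thin slices
      m <- matrix(grp, nrow = d[1] * d[2], ncol = r)
      counts <- sapply(0:(v$n_classes - 1L), function(cl) rowSums(m == cl))
      out[, , k] <- max.col(counts, ties.method = "first") - 1L
    } else {
      out[, , k] <- rowMeans(matrix(grp, nrow = d[1] * d[2], ncol = r))
    }
  }
  new_spacing <- c(v$spacing[1:2], spec$target_z_spacing)
  # thick-slice centres sit at the centroid of their constituent thin slices
  origin <- v$origin + as.numeric(v$axes %*% c(0, 0, (r - 1) / 2 * v$spacing[3]))
  if (is_lab) cmr_labelmap(out, new_spacing, origin, v$axes, v$n_classes)
  else cmr_volume(out, new_spacing, origin, v$axes)
}

#' Random in-plane inter-slice shift
#'
#' Each short-axis slice is independently translated in-plane by an integer
#' voxel shift drawn uniformly within `max_shift_mm`; voxels shifted out of
#' frame are zero-filled. The same seed yields identical shifts, so a paired
#' volume and label map can be misaligned consistently.
#'
#' @inheritParams thick_slice
#' @param shifts optional integer matrix (n_slices x 2) of voxel shifts to
#'   apply, overriding the random draw.
#' @return list with the shifted object (`data`) and the applied per-slice
#'   voxel `shifts` (n_slices x 2, in voxels) plus `shifts_mm`.
#' @export
inter_slice_shift <- function(v, spec = artefact_spec(), shifts = NULL) {
  stopifnot(inherits(v, "cmr_volume"))
  d <- dim(v$data)
  max_vox <- floor(spec$max_shift_mm / v$spacing[1:2])
  if (is.null(shifts)) {
    draw <- function(m, n) {
      vals <- seq.int(-m, m)
      vals[sample.int(length(vals), n, replace = TRUE)]
    }
    shifts <- with_seed(spec$rng_seed,
                        cbind(draw(max_vox[1], d[3]), draw(max_vox[2], d[3])))
  }
  shifts <- matrix(as.integer(shifts), ncol = 2L)
  is_lab <- inherits(v, "cmr_labelmap")
  out <- array(if (is_lab) 0L else 0, d)
  for (k in seq_len(d[3])) {
    sx <- shifts[k, 1]; sy <- shifts[k, 2]
    xi <- seq_len(d[1]) - sx
    yi <- seq_len(d[2]) - sy
    okx <- xi >= 1L & xi <= d[1]
    oky <- yi >= 1L & yi <= d[2]
    out[which(okx), which(oky), k] <- v$data[xi[okx], yi[oky], k]
  }
  obj <- if (is_lab) cmr_labelmap(out, v$spacing, v$origin, v$axes, v$n_classes)
         else cmr_volume(out, v$spacing, v$origin, v$axes)
  list(data = obj, shifts = shifts, shifts_mm = sweep(shifts, 2L, v$spacing[1:2], "*"))
}

#' Corrupt a paired volume and label map with low-resolution artefacts
#'
#' Composition thick-slice downsampling, then inter-slice shift, then optional
#' apical truncation (the most apical thick slices are removed, emulating lack
#' of slice coverage). The identical geometric degradation is applied to the
#' volume and the label map; all parameters and per-slice shifts are returned
#' as metadata.
#'
#' @param v a [cmr_volume()].
#' @param lab the paired [cmr_labelmap()] on the same lattice.
#' @param spec an [artefact_spec()].
#' @param apex_low if `TRUE` (default) the apex is at the low-z end of the
#'   stack, and truncation removes the first slices.
#' @return list with `volume`, `labels`, and `meta` (spec, per-slice shifts).
#' @export
corrupt <- function(v, lab, spec = artefact_spec(), apex_low = TRUE) {
  assert_same_lattice(v, lab, "volume and label map")
  tv <- thick_slice(v, spec)
  tl <- thick_slice(lab, spec)
  sv <- inter_slice_shift(tv, spec)
  sl <- inter_slice_shift(tl, spec, shifts = sv$shifts)
  ov <- sv$data
  ol <- sl$data
  ns <- spec$apical_truncation_slices
  if (ns > 0L) {
    d <- dim(ov$data)
    if (ns >= d[3]) stop("truncation removes all slices")
    keep <- if (apex_low) (ns + 1L):d[3] else seq_len(d[3] - ns)
    new_origin <- if (apex_low)
      ov$origin + as.numeric(ov$axes %*% c(0, 0, ns * ov$spacing[3])) else ov$origin
    ov <- cmr_volume(ov$data[, , keep, drop = FALSE], ov$spacing, new_origin, ov$axes)
    ol <- cmr_labelmap(ol$data[, , keep, drop = FALSE], ol$spacing, new_origin,
                       ol$axes, ol$n_classes)
  }
  list(volume = ov, labels = ol,
       meta = list(spec = spec, shifts = sv$shifts, shifts_mm = sv$shifts_mm,
                   truncated_slices = ns, apex_low = apex_low))
}
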