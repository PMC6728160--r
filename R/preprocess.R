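#' Preprocessing specification
#'
#' Target common grid dimensions, intensity clipping percentiles and output
#' range used to standardise volumes before they enter the network.
#'
#' @param target_dims integer length-3 common grid size (default 192x192x80).
#' @param clip_percentiles low/high percentiles defining intensity outliers.
#' @param out_range output intensity range after rescaling.
#' @param centre_crop if `TRUE`, volumes larger than `target_dims` are centre
#'   cropped instead of raising an error.
#' @return A `preproc_spec` list.
#' @export
preproc_spec <- function(target_dims = c(192L, 192L, 80L),
                         clip_percentiles = c(1, 99),
                         out_range = c(0, 1),
                         centre_crop = FALSE) {
  target_dims <- as.integer(target_dims)
  if (length(target_dims) != 3L || any(target_dims < 1L)) stop("invalid 'target_dims'")
  if (clip_percentiles[1] >= clip_percentiles[2]) stop("percentile low must be < high")
  structure(list(target_dims = target_dims, clip_percentiles = clip_percentiles,
                 out_range = out_range, centre_crop = isTRUE(centre_crop)),
            class = "preproc_spec")
}

#' Standardise a volume: clip intensities, rescale and zero-pad
#'
#' Intensities at or below the lower clipping percentile map to the low end of
#' `out_range` and those at or above the upper percentile to the high end;
#' degenerate (constant) volumes map to the low end everywhere. The grid is
#' then zero-padded symmetrically to `target_dims`. Inputs exceeding the
#' target in any axis raise an error unless `centre_crop` was requested in the
#' spec.
#'
#' @param v a [cmr_volume()].
#' @param spec a [preproc_spec()].
#' @return A [cmr_volume()] with dimensions `spec$target_dims`.
#' @export
preprocess <- function(v, spec = preproc_spec()) {
  stopifnot(inherits(v, "cmr_volume"), inherits(spec, "preproc_spec"))
  q <- quantile(v$data, probs = spec$clip_percentiles / 100, names = FALSE)
  lo <- spec$out_range[1]
  hi <- spec$out_range[2]
  dat <- if (q[2] > q[1]) {
    lo + (pmin(pmax(v$data, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * (hi - lo)
  } else {
    array(lo, dim(v$data))
  }
  d <- dim(v$data)
  td <- spec$target_dims
  origin <- v$origin
  if (any(d > td)) {
    if (!spec$centre_crop)
      stop_bivseg(sprintf("input dims (%s) exceed target dims (%s); set centre_crop",
                          paste(d, collapse = "x"), paste(td, collapse = "x")),
                  "bivseg_spec_error")
    start <- pmax(0L, (d - td) %/% 2L)
    keep <- pmin(d, td)
    dat <- dat[start[1] + seq_len(keep[1]), start[2] + seq_len(keep[2]),
               start[3] + seq_len(keep[3]), drop = FALSE]
    origin <- origin + as.numeric(v$axes %*% (v$spacing * start))
    d <- dim(dat)
  }
  pad_low <- (td - d) %/% 2L
  out <- array(lo, td)
  out[pad_low[1] + seq_len(d[1]), pad_low[2] + seq_len(d[2]),
      pad_low[3] + seq_len(d[3])] <- dat
  origin <- origin - as.numeric(v$axes %*% (v$spacing * pad_low))
  cmr_volume(out, v$spacing, origin, v$axes)
}

#' Resample a volume or label map to a new voxel spacing
#'
#' Volumes are interpolated trilinearly, label maps by nearest neighbour (the
#' label set is closed under resampling). The world extent and origin are
#' preserved.
#'
#' @param v a [cmr_volume()] or [cmr_labelmap()].
#' @param new_spacing numeric length-3 target spacing (mm), strictly positive.
#' @return Object of the same class on the new lattice.
#' @export
resample <- function(v, new_spacing) UseMethod("resample")

resample_core <- function(v, new_spacing, nearest) {
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3L)
  if (length(new_spacing) != 3L || any(!is.finite(new_spacing)) || any(new_spacing <= 0))
    stop("'new_spacing' must be 3 strictly positive values")
  d <- dim(v$data)
  nd <- pmax(1L, as.integer(round(d * v$spacing / new_spacing)))
  ratio <- new_spacing / v$spacing
  out <- cpp_warp_affine(as.numeric(v$data), d, diag(ratio), c(0, 0, 0),
                         nd, nearest, 0)
  list(data = array(out, nd), spacing = new_spacing)
}

#' @export
resample.cmr_volume <- function(v, new_spacing) {
  r <- resample_core(v, new_spacing, nearest = FALSE)
  cmr_volume(r$data, r$spacing, v$origin, v$axes)
}

#' @export
resample.cmr_labelmap <- function(v, new_spacing) {
  r <- resample_core(v, new_spacing, nearest = TRUE)
  cmr_labelmap(r$data, r$spacing, v$origin, v$axes, n_classes = v$n_classes)
}

#' Random 3D augmentation of a (volume, labels, landmarks) triple
#'
#' Applies one random affine transform -- in-plane translation, isotropic
#' scaling, and rotation about one random grid axis through the central voxel
#' -- plus a random intensity gain, consistently to all three inputs. The
#' volume is warped with trilinear interpolation, the label map with nearest
#' neighbour, and landmark points are transformed exactly (not resampled).
#' Neither shearing nor flipping is applied. Deterministic per `rng_seed`.
#'
#' @param v a [cmr_volume()].
#' @param lab optional [cmr_labelmap()] on the same lattice.
#' @param lm optional [landmark_set()].
#' @param rng_seed integer seed for the parameter draw.
#' @param params optional explicit parameter list with elements `trans`
#'   (length-2, in-plane voxels), `scale`, `axis` (1, 2 or 3), `angle_deg`,
#'   `gain`; overrides the random draw.
#' @param trans_range,scale_range,rot_range,intensity_range draw ranges:
#'   translation is uniform on `[-trans_range, trans_range]` voxels per
#'   in-plane axis, scale and gain uniform on their ranges, rotation uniform
#'   on `[-rot_range, rot_range]` degrees.
#' @return list with elements `volume`, `labels`, `landmarks`, `params`.
#' @export
augment <- function(v, lab = NULL, lm = NULL, rng_seed = 1L, params = NULL,
                    trans_range = 10, scale_range = c(0.9, 1.1), rot_range = 15,
                    intensity_range = c(0.9, 1.1)) {
  stopifnot(inherits(v, "cmr_volume"))
  if (!is.null(lab)) assert_same_lattice(v, lab, "volume and label map")
  if (is.null(params)) {
    params <- with_seed(rng_seed, list(
      trans = runif(2, -trans_range, trans_range),
      scale = runif(1, scale_range[1], scale_range[2]),
      axis = sample(3L, 1L),
      angle_deg = runif(1, -rot_range, rot_range),
      gain = runif(1, intensity_range[1], intensity_range[2])))
  }
  d <- dim(v$data)
  B <- v$axes %*% diag(v$spacing)      # voxel -> world linear part
  centre <- as.numeric(vox2world(v, (d - 1) / 2))
  th <- params$angle_deg * pi / 180
  R <- diag(3)
  ax <- params$axis
  cs <- cos(th); sn <- sin(th)
  idx <- setdiff(1:3, ax)
  R[idx, idx] <- matrix(c(cs, sn, -sn, cs), 2L)
  A <- v$axes %*% (params$scale * R) %*% t(v$axes)
  textra <- as.numeric(v$axes %*% c(params$trans * v$spacing[1:2], 0))
  b <- centre - A %*% centre + textra
  # pull-back voxel map for resampling: src_idx = Minv out_idx + tinv
  Fm <- solve(B) %*% A %*% B
  Ft <- as.numeric(solve(B) %*% (A %*% v$origin + b - v$origin))
  Minv <- solve(Fm)
  tinv <- as.numeric(-Minv %*% Ft)
  wdat <- array(cpp_warp_affine(as.numeric(v$data), d, Minv, tinv, d, FALSE, 0), d)
  out_v <- cmr_volume(wdat * params$gain, v$spacing, v$origin, v$axes)
  out_l <- NULL
  if (!is.null(lab)) {
    ldat <- array(cpp_warp_affine(as.numeric(lab$data), d, Minv, tinv, d, TRUE, 0), d)
    out_l <- cmr_labelmap(ldat, lab$spacing, lab$origin, lab$axes, lab$n_classes)
  }
  out_m <- NULL
  if (!is.null(lm)) {
    new_world <- sweep(lm$world %*% t(A), 2L, as.numeric(b), "+")
    new_vox <- round(world2vox(v, new_world))
    new_vox <- pmin(pmax(new_vox, 0), matrix(d - 1L, nrow(new_vox), 3L, byrow = TRUE))
    rownames(new_vox) <- rownames(lm$voxel)
    out_m <- landmark_set(new_vox, new_world)
  }
  list(volume = out_v, labels = out_l, landmarks = out_m, params = params)
}
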