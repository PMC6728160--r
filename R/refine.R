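#' Label consistency between two aligned label maps
#'
#' The sum over classes of the diagonal of the joint label probability
#' (estimated from the joint histogram over the overlap region), i.e. the
#' fraction of voxels assigned the same label in both maps.
#'
#' @param a,b [cmr_labelmap()] objects (or integer arrays) on the same
#'   lattice; `b` is typically an atlas segmentation already warped onto `a`.
#' @param mask optional logical array restricting the overlap region.
#' @return scalar in `[0, 1]`.
#' @export
label_consistency <- function(a, b, mask = NULL) {
  da <- if (inherits(a, "cmr_labelmap")) a$data else a
  db <- if (inherits(b, "cmr_labelmap")) b$data else b
  if (!identical(dim(da), dim(db)))
    stop_bivseg("label maps must share the same lattice", "bivseg_shape_error")
  if (inherits(a, "cmr_labelmap") && inherits(b, "cmr_labelmap"))
    assert_same_lattice(a, b, "label maps")
  if (!is.null(mask)) {
    da <- da[mask]
    db <- db[mask]
  }
  mean(da == db)
}

# Studholme normalised mutual information (H(A)+H(B))/H(A,B) over the discrete
# joint label histogram; equals 2 for identical non-constant label maps.
nmi_labels <- function(a, b) {
  n <- length(a)
  joint <- table(a, b) / n
  pj <- joint[joint > 0]
  pa <- rowSums(joint); pa <- pa[pa > 0]
  pb <- colSums(joint); pb <- pb[pb > 0]
  Ha <- -sum(pa * log(pa))
  Hb <- -sum(pb * log(pb))
  Hab <- -sum(pj * log(pj))
  if (Hab == 0) return(2)  # both constant and identical partitioning
  (Ha + Hb) / Hab
}

#' Select the most similar atlases for a target segmentation
#'
#' Each atlas segmentation is warped to the target space through the affine
#' transform computed from its landmarks and the target landmarks; the
#' normalised mutual information (Studholme form, on the discrete joint label
#' histogram) between the target segmentation and each warped atlas
#' segmentation is computed, and the `L` most similar atlases are returned
#' (deterministic ordering: ties broken by bank position).
#'
#' @param target_seg [cmr_labelmap()] of the target.
#' @param bank an `atlas_bank`.
#' @param target_lm [landmark_set()] of the target.
#' @param L number of atlases to keep; truncated with a warning if larger
#'   than the bank.
#' @return list of selected entries, each with `atlas`, `transform`
#'   (atlas -> target world affine), `nmi` and `warped_labels`.
#' @export
select_atlases <- function(target_seg, bank, target_lm, L = 5L) {
  stopifnot(inherits(bank, "atlas_bank"), length(bank) >= 1L)
  if (L > length(bank)) {
    warning(sprintf("L = %d exceeds bank size %d; using all atlases", L, length(bank)))
    L <- length(bank)
  }
  entries <- lapply(bank, function(atl) {
    tr <- affine_from_landmarks(atl$landmarks, target_lm)
    warped <- warp_to_grid(atl$labels, target_seg, tr)
    list(atlas = atl, transform = tr, nmi = nmi_labels(target_seg$data, warped$data),
         warped_labels = warped)
  })
  ord <- order(-vapply(entries, `[[`, 0, "nmi"), seq_along(entries))
  entries[ord[seq_len(L)]]
}

#' Label-consistency free-form deformation registration
#'
#' Registers an atlas segmentation onto a target segmentation by maximising
#' label consistency with a multi-scale B-spline free-form deformation,
#' initialised by a landmark affine transform. The optimisation uses a
#' differentiable surrogate: atlas labels are lifted to one-hot channel
#' fields (Gaussian-smoothed per level), warped with trilinear interpolation,
#' and the mean probability assigned to the target's label is maximised by
#' gradient ascent with a backtracking line search, which makes the surrogate
#' agreement non-decreasing across iterations within each level. If the final
#' hard-label agreement does not improve on the affine initialisation the
#' identity deformation is returned.
#'
#' @param target_seg [cmr_labelmap()], the fixed image.
#' @param atlas_seg [cmr_labelmap()] on its own lattice, the moving image.
#' @param init [affine_transform()] mapping atlas world to target world.
#' @param levels_mm control-point spacings of the coarse-to-fine schedule: a
#'   vector (isotropic spacing per level) or an `n_levels x 3` matrix of
#'   per-axis spacings. The default (40, 20, 10 mm, plus a second pass at the
#'   finest spacing with sharper channel smoothing) is isotropic; for targets
#'   whose long-axis resolution is corrupted, an anisotropic schedule with
#'   coarse z spacing keeps the warp smooth along the long axis.
#' @param smooth_sigma_mm Gaussian smoothing of the one-hot channels per
#'   level (mm).
#' @param max_iter maximum L-BFGS iterations per level, spent in segments of
#'   `segment_iters` so the accepted objective trace can be recorded; the
#'   trace is non-decreasing by construction.
#' @param segment_iters iterations per recorded segment.
#' @param tol stop a level when the surrogate gain over a segment falls below
#'   this.
#' @param mask optional logical array on the target lattice restricting the
#'   objective to covered voxels; voxels outside it (e.g. slices never
#'   acquired for a truncated low-resolution target) carry no information and
#'   the deformation there is governed by B-spline smoothness alone.
#' @param lambda small Tikhonov penalty on the control-point displacements
#'   (per squared voxel). The probability surrogate can otherwise gain
#'   marginally by drifting samples from region boundaries towards interiors
#'   without changing any hard label; the penalty removes that drift and
#'   keeps an already-registered pair exactly at the identity.
#' @return An `ffd_transform`: the affine, per-level control lattices, the
#'   dense displacement field on the target lattice (atlas voxel units), the
#'   surrogate history and the initial/final hard-label agreements.
#' @export
register_ffd <- function(target_seg, atlas_seg, init = affine_transform(),
                         levels_mm = c(40, 20, 10, 10),
                         smooth_sigma_mm = c(4, 2, 1, 0.6),
                         max_iter = 60L, segment_iters = 10L, tol = 1e-6,
                         mask = NULL, lambda = 3e-6) {
  stopifnot(inherits(target_seg, "cmr_labelmap"), inherits(atlas_seg, "cmr_labelmap"))
  if (abs(det(init$A)) < 1e-10)
    stop_bivseg("initial affine is singular", "bivseg_degeneracy_error")
  K <- max(target_seg$n_classes, atlas_seg$n_classes)
  tdims <- dim(target_seg$data)
  pdims <- dim(atlas_seg$data)
  vm <- voxmap_from_world_affine(atlas_seg, target_seg, init)
  truth <- as.integer(target_seg$data)
  onehot <- array(0, c(pdims, K))
  for (k in seq_len(K) - 1L)
    onehot[, , , k + 1L] <- as.numeric(atlas_seg$data == k)
  t_onehot <- array(0, c(tdims, K))
  for (k in seq_len(K) - 1L)
    t_onehot[, , , k + 1L] <- as.numeric(target_seg$data == k)
  base <- numeric(prod(tdims) * 3)
  has_base <- FALSE
  levels <- list()
  history <- list()
  cmask <- if (is.null(mask)) logical(0) else as.logical(mask)
  hard_agree <- function(disp) {
    lab <- if (is.null(disp))
      cpp_warp_affine(as.numeric(atlas_seg$data), pdims, vm$M, vm$t, tdims,
                      TRUE, 0)
    else
      cpp_warp_disp(as.numeric(atlas_seg$data), pdims, vm$M, vm$t, disp,
                    tdims, TRUE, 0)
    if (length(cmask)) mean(lab[cmask] == truth[cmask]) else mean(lab == truth)
  }
  agree0 <- hard_agree(NULL)
  if (agree0 >= 1 - 1e-12) {
    # already in perfect agreement: nothing to optimise, return the identity
    return(structure(list(affine = init, levels = list(),
                          disp = array(0, c(tdims, 3L)),
                          target_spacing = target_seg$spacing,
                          history = list(),
                          agreement = c(initial = agree0, final = agree0)),
                     class = "ffd_transform"))
  }
  if (!is.matrix(levels_mm))
    levels_mm <- matrix(rep(levels_mm, 3L), ncol = 3L)
  n_levels <- nrow(levels_mm)
  if (length(smooth_sigma_mm) < n_levels)
    smooth_sigma_mm <- c(smooth_sigma_mm,
                         rep(smooth_sigma_mm[length(smooth_sigma_mm)],
                             n_levels - length(smooth_sigma_mm)))
  for (lv in seq_len(n_levels)) {
    delta <- levels_mm[lv, ] / target_seg$spacing
    nc <- as.integer(floor((tdims - 1) / delta) + 4L)
    sig <- smooth_sigma_mm[lv] / atlas_seg$spacing
    prob <- array(0, c(pdims, K))
    for (k in seq_len(K))
      prob[, , , k] <- array(cpp_gaussian_smooth3(as.numeric(onehot[, , , k]),
                                                  pdims, sig), pdims)
    prob <- as.numeric(prob)
    # both label maps are smoothed: the objective is the soft diagonal of the
    # joint label probability, optimal at identity for identical inputs
    sig_t <- smooth_sigma_mm[lv] / target_seg$spacing
    qprob <- array(0, c(tdims, K))
    for (k in seq_len(K))
      qprob[, , , k] <- array(cpp_gaussian_smooth3(as.numeric(t_onehot[, , , k]),
                                                   tdims, sig_t), tdims)
    qprob <- as.numeric(qprob)
    fn <- function(cf) -cpp_ffd_obj_grad(prob, pdims, K, qprob, tdims, vm$M,
                                         vm$t, base, has_base, cf, nc, delta,
                                         FALSE, cmask)$value +
      lambda * sum(cf^2)
    gr <- function(cf) -as.numeric(cpp_ffd_obj_grad(prob, pdims, K, qprob,
                                                    tdims, vm$M, vm$t, base,
                                                    has_base, cf, nc, delta,
                                                    TRUE, cmask)$grad) +
      2 * lambda * cf
    coef <- numeric(prod(nc) * 3)
    cur <- -fn(coef)
    hist_lv <- cur
    # per-level displacement bound of 0.4 control spacings guards against
    # grid folding and runaway control points in flat-gradient regions
    bound <- 0.4 * rep(delta, each = prod(nc))
    n_seg <- max(1L, ceiling(max_iter / segment_iters))
    for (sg in seq_len(n_seg)) {
      res <- stats::optim(coef, fn, gr, method = "L-BFGS-B",
                          lower = -bound, upper = bound,
                          control = list(maxit = segment_iters))
      val <- -res$value
      # only segments with a meaningful gain are accepted, so the recorded
      # agreement trace is strictly increasing and near-flat wandering of
      # control points (e.g. when already registered) is rejected
      if (val <= cur + tol) break
      coef <- res$par
      cur <- val
      hist_lv <- c(hist_lv, cur)
    }
    base <- base + as.numeric(cpp_ffd_eval_dense(coef, nc, delta, tdims))
    has_base <- TRUE
    levels[[lv]] <- list(delta = delta, nc = nc, coef = array(coef, c(nc, 3L)))
    history[[lv]] <- hist_lv
  }
  # acceptance gate on the hard-label agreement
  agree1 <- hard_agree(base)
  if (agree1 < agree0) {
    base <- numeric(prod(tdims) * 3)
    levels <- list()
    agree1 <- agree0
  }
  structure(list(affine = init, levels = levels,
                 disp = array(base, c(tdims, 3L)),
                 target_spacing = target_seg$spacing,
                 history = history,
                 agreement = c(initial = agree0, final = agree1)),
            class = "ffd_transform")
}

#' @export
print.ffd_transform <- function(x, ...) {
  cat(sprintf("<ffd_transform> %d levels, agreement %.4f -> %.4f, max |u| %.2f vox\n",
              length(x$levels), x$agreement[1], x$agreement[2], max(abs(x$disp))))
  invisible(x)
}

#' Warp a volume or label map through an affine + FFD transform
#'
#' @param v the atlas-space [cmr_volume()] or [cmr_labelmap()] to warp.
#' @param ffd an `ffd_transform` from [register_ffd()].
#' @param ref the target grid object.
#' @return the warped object on `ref`'s lattice (labels nearest-neighbour,
#'   volumes trilinear).
#' @export
warp_ffd <- function(v, ffd, ref) {
  vm <- voxmap_from_world_affine(v, ref, ffd$affine)
  nearest <- inherits(v, "cmr_labelmap")
  dat <- cpp_warp_disp(as.numeric(v$data), dim(v$data), vm$M, vm$t,
                       as.numeric(ffd$disp), dim(ref$data), nearest, 0)
  if (nearest)
    cmr_labelmap(array(dat, dim(ref$data)), ref$spacing, ref$origin, ref$axes,
                 v$n_classes)
  else cmr_volume(array(dat, dim(ref$data)), ref$spacing, ref$origin, ref$axes)
}

#' Non-local label fusion specification
#'
#' @param patch_radius patch radius in voxels (patch side `2r+1`).
#' @param window_radius search-window radius in voxels.
#' @param h Gaussian kernel bandwidth; `NULL` selects it per target as the
#'   mean over voxels of the minimum patch distance across atlases
#'   (scale-adaptive).
#' @param L number of atlases used for selection/fusion.
#' @return A `fusion_spec`.
#' @export
fusion_spec <- function(patch_radius = 2L, window_radius = 2L, h = NULL, L = 5L) {
  stopifnot(patch_radius >= 0, window_radius >= 0, L >= 1)
  if (!is.null(h)) check_scalar_num(h, "h", positive = TRUE)
  structure(list(patch_radius = as.integer(patch_radius),
                 window_radius = as.integer(window_radius), h = h,
                 L = as.integer(L)),
            class = "fusion_spec")
}

#' Non-local patch-based label fusion
#'
#' Weighted voting over warped atlases: for each target voxel `x` and window
#' position `y`, each atlas casts a vote for its label at `y` with weight
#' `exp(-||f_x - f_{n,y}||_F^2 / h)` computed between the target patch at `x`
#' and the atlas patch at `y`; the fused label is the argmax of the summed
#' votes (ties to the lower class index). Patches are clipped at grid borders
#' with consistent normalisation.
#'
#' @param target_vol [cmr_volume()] on the target lattice.
#' @param warped list of warped atlases, each a list with `volume` and
#'   `labels` on the target lattice.
#' @param spec a [fusion_spec()].
#' @return fused [cmr_labelmap()].
#' @export
fuse_labels <- function(target_vol, warped, spec = fusion_spec()) {
  if (length(warped) == 0L) stop("empty atlas list")
  for (w in warped) {
    assert_same_lattice(target_vol, w$volume, "target and warped atlas volume")
    assert_same_lattice(target_vol, w$labels, "target and warped atlas labels")
  }
  d <- dim(target_vol$data)
  K <- max(vapply(warped, function(w) w$labels$n_classes, 0L))
  vols <- lapply(warped, function(w) as.numeric(w$volume$data))
  labs <- lapply(warped, function(w) as.integer(w$labels$data))
  h <- spec$h
  if (is.null(h)) {
    h <- cpp_mean_min_patch_dist(as.numeric(target_vol$data), d, vols,
                                 spec$patch_radius)
    h <- max(h, 1e-8)
  }
  fused <- cpp_fuse_labels(as.numeric(target_vol$data), d, vols, labs, K,
                           spec$patch_radius, spec$window_radius, h)
  out <- cmr_labelmap(array(fused, d), target_vol$spacing, target_vol$origin,
                      target_vol$axes, K)
  attr(out, "h") <- h
  out
}

refine_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("refine stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Shape-refine a segmentation with a bank of high-resolution atlases
#'
#' The explicit anatomical shape prior: landmark-initialised affine
#' alignment, NMI atlas selection, label-consistency FFD registration of each
#' selected atlas, warping of atlas volumes and labels to the target space,
#' and non-local patch-based label fusion.
#'
#' @param target_vol [cmr_volume()] on the high-resolution target lattice.
#' @param target_seg initial [cmr_labelmap()] (e.g. a network prediction).
#' @param target_lm [landmark_set()] of the target.
#' @param bank an `atlas_bank`.
#' @param spec a [fusion_spec()] (also supplies `L`).
#' @param reg_args list of extra arguments for [register_ffd()].
#' @return refined [cmr_labelmap()] with a `scores` attribute (per-atlas NMI
#'   and registration agreements).
#' @export
refine <- function(target_vol, target_seg, target_lm, bank,
                   spec = fusion_spec(), reg_args = list()) {
  assert_same_lattice(target_vol, target_seg, "target volume and segmentation")
  sel <- refine_stage("atlas selection",
                      select_atlases(target_seg, bank, target_lm, spec$L))
  warped <- lapply(sel, function(e) {
    ffd <- refine_stage(paste0("registration (", e$atlas$id, ")"),
                        do.call(register_ffd,
                                c(list(target_seg, e$atlas$labels, e$transform),
                                  reg_args)))
    refine_stage(paste0("warping (", e$atlas$id, ")"),
                 list(volume = warp_ffd(e$atlas$volume, ffd, target_seg),
                      labels = warp_ffd(e$atlas$labels, ffd, target_seg),
                      agreement = ffd$agreement))
  })
  fused <- refine_stage("label fusion", fuse_labels(target_vol, warped, spec))
  attr(fused, "scores") <- data.frame(
    atlas = vapply(sel, function(e) e$atlas$id, ""),
    nmi = vapply(sel, `[[`, 0, "nmi"),
    agreement_initial = vapply(warped, function(w) w$agreement[1], 0),
    agreement_final = vapply(warped, function(w) w$agreement[2], 0))
  fused
}
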