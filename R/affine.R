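#' Affine world transform (12 degrees of freedom)
#'
#' A 3x3 linear part plus a translation acting on world coordinates in mm.
#'
#' @param A 3x3 invertible matrix.
#' @param t length-3 translation (mm).
#' @return An `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3L, 3L)) || !all(is.finite(A)))
    stop("'A' must be a finite 3x3 matrix")
  if (abs(det(A)) < 1e-10)
    stop_bivseg("affine linear part is singular", "bivseg_degeneracy_error")
  structure(list(A = A, t = as.numeric(t)), class = "affine_transform")
}

#' Apply an affine transform to points
#' @param tr an [affine_transform()].
#' @param pts numeric matrix (n x 3) of world coordinates (mm).
#' @return transformed matrix (n x 3).
#' @export
apply_affine <- function(tr, pts) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3L)
  sweep(pts %*% t(tr$A), 2L, tr$t, "+")
}

#' Invert an affine transform
#' @param tr an [affine_transform()].
#' @return the inverse `affine_transform`.
#' @export
affine_inverse <- function(tr) {
  Ai <- solve(tr$A)
  affine_transform(Ai, -as.numeric(Ai %*% tr$t))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(cbind(x$A, t = x$t))
  invisible(x)
}

#' Least-squares affine transform between two landmark sets
#'
#' Computes the 12-degree-of-freedom affine transform minimising
#' `sum_i || A src_i + t - dst_i ||^2` over the landmarks shared by name.
#' This is a convex least-squares problem with a unique solution whenever at
#' least 4 non-coplanar correspondences are available; when `dst` is an exact
#' affine image of `src` the transform is recovered exactly (zero residual).
#'
#' @param src,dst [landmark_set()] objects (or matrices with landmark
#'   rownames); the transform maps `src` onto `dst`.
#' @return An [affine_transform()] with attributes `residual` (sum of squared
#'   residuals, mm^2) and `n_points`.
#' @export
affine_from_landmarks <- function(src, dst) {
  get_pts <- function(x) if (inherits(x, "landmark_set")) x$world else as.matrix(x)
  sp <- get_pts(src)
  dp <- get_pts(dst)
  shared <- intersect(rownames(sp), rownames(dp))
  if (length(shared) < 4L)
    stop_bivseg(sprintf("need >= 4 shared landmarks, have %d", length(shared)),
                "bivseg_degeneracy_error")
  sp <- sp[shared, , drop = FALSE]
  dp <- dp[shared, , drop = FALSE]
  ctr <- sweep(sp, 2L, colMeans(sp))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-8 * max(sv[1], 1e-12))
    stop_bivseg("landmark configuration is coplanar; affine is not determined",
                "bivseg_degeneracy_error")
  X <- cbind(sp, 1)
  B <- qr.solve(X, dp)
  res <- sum((X %*% B - dp)^2)
  out <- affine_transform(t(B[1:3, , drop = FALSE]), B[4, ])
  attr(out, "residual") <- res
  attr(out, "n_points") <- length(shared)
  out
}

# Voxel-space pull-back map: src_idx = M %*% dst_idx + t, where `world_affine`
# maps src world coordinates to dst world coordinates (e.g. atlas -> target).
voxmap_from_world_affine <- function(src_grid, dst_grid, world_affine) {
  Bs <- src_grid$axes %*% diag(src_grid$spacing)
  Bd <- dst_grid$axes %*% diag(dst_grid$spacing)
  Ai <- solve(world_affine$A)
  M <- solve(Bs) %*% Ai %*% Bd
  t <- as.numeric(solve(Bs) %*%
                    (Ai %*% (dst_grid$origin - world_affine$t) - src_grid$origin))
  list(M = M, t = t)
}

# Warp a volume/label map onto the lattice of `ref` through a world affine
# mapping v's world onto ref's world.
warp_to_grid <- function(v, ref, world_affine = affine_transform()) {
  vm <- voxmap_from_world_affine(v, ref, world_affine)
  nearest <- inherits(v, "cmr_labelmap")
  dat <- cpp_warp_affine(as.numeric(v$data), dim(v$data), vm$M, vm$t,
                         dim(ref$data), nearest, 0)
  if (nearest)
    cmr_labelmap(array(dat, dim(ref$data)), ref$spacing, ref$origin, ref$axes,
                 v$n_classes)
  else cmr_volume(array(dat, dim(ref$data)), ref$spacing, ref$origin, ref$axes)
}

#' Resample a volume or label map onto the lattice of a reference grid
#'
#' Identity world transform: the input is sampled at the reference grid's
#' world coordinates (trilinear for volumes, nearest neighbour for label
#' maps), zero-filled outside the input extent.
#'
#' @param v a [cmr_volume()] or [cmr_labelmap()].
#' @param ref the reference grid object.
#' @return Object of the same class as `v` on `ref`'s lattice.
#' @export
resample_to_grid <- function(v, ref) warp_to_grid(v, ref, affine_transform())
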