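#' Global soft Dice loss
#'
#' The differentiable Dice segmentation loss: one global quotient over all
#' classes and voxels per sample,
#' \deqn{L_D = -\sum_i \frac{2\sum_k\sum_j 1\{r_j=k\} P(r_j=k)}
#'   {\sum_k\sum_j (1\{r_j=k\}^2 + P^2(r_j=k) + \epsilon)}}
#' so a perfect one-hot prediction approaches -1 per sample and a completely
#' disagreeing one-hot prediction gives 0. `eps` guards against division by
#' zero.
#'
#' @param prob 4D array `(nx, ny, nz, K)` of per-voxel class probabilities, or
#'   a list of such arrays (one per sample).
#' @param truth [cmr_labelmap()] or integer array of 0-based labels (or a
#'   matching list).
#' @param eps small positive smoothing constant.
#' @param per_class if `TRUE`, use the per-class variant (one quotient per
#'   class, summed), which weights every class equally instead of every
#'   voxel; the default is the single global quotient.
#' @return scalar loss in `(-n_samples, 0]` (global) or `(-n_samples * K, 0]`
#'   (per class).
#' @export
dice_loss <- function(prob, truth, eps = 1e-5, per_class = FALSE) {
  if (is.list(prob) && !is.array(prob)) {
    stopifnot(is.list(truth), length(prob) == length(truth))
    return(sum(mapply(dice_loss, prob, truth,
                      MoreArgs = list(eps = eps, per_class = per_class))))
  }
  tr <- if (inherits(truth, "cmr_labelmap")) truth$data else truth
  dp <- dim(prob)
  if (length(dp) != 4L || !identical(dp[1:3], dim(tr)[1:3]))
    stop_bivseg("probability map and truth lattices do not match",
                "bivseg_shape_error")
  K <- dp[4]
  if (max(tr) >= K) stop_bivseg("truth classes exceed probability channels",
                                "bivseg_shape_error")
  V <- prod(dp[1:3])
  Pm <- matrix(prob, V, K)
  idx <- cbind(seq_len(V), as.integer(tr) + 1L)
  if (per_class) {
    loss <- 0
    for (k in seq_len(K)) {
      mk <- as.integer(tr) + 1L == k
      loss <- loss - 2 * sum(Pm[idx][mk]) / (sum(mk) + sum(Pm[, k]^2) + V * eps)
    }
    return(loss)
  }
  num <- 2 * sum(Pm[idx])
  den <- V + sum(Pm^2) + V * K * eps
  -num / den
}

#' Analytic gradient of [dice_loss()] with respect to the probabilities
#'
#' @inheritParams dice_loss
#' @return array of the same shape as `prob`.
#' @export
dice_loss_grad <- function(prob, truth, eps = 1e-5) {
  tr <- if (inherits(truth, "cmr_labelmap")) truth$data else truth
  dp <- dim(prob)
  K <- dp[4]
  V <- prod(dp[1:3])
  Pm <- matrix(prob, V, K)
  idx <- cbind(seq_len(V), as.integer(tr) + 1L)
  N <- sum(Pm[idx])
  D <- V + sum(Pm^2) + V * K * eps
  G <- (4 * N / D^2) * Pm
  G[idx] <- G[idx] - 2 / D
  array(G, dp)
}

#' Class-balancing weights for landmark classification
#'
#' For each landmark class `k` (including background, class 0) the weight is
#' exactly `w_k = 1 - |Y_k| / |Y|`, where `|Y_k|` is the number of voxels of
#' class `k` and `|Y|` the total voxel count. Landmark classes (few voxels)
#' receive weights close to 1 and the background a weight close to 0, which
#' balances the loss contributions of the two groups.
#'
#' @param truth_lm integer array of 0-based landmark class labels
#'   (0 = background, 1..6 = landmarks).
#' @param n_classes number of classes (default 7).
#' @return named numeric vector of weights, classes `0 .. n_classes-1`.
#' @export
landmark_weights <- function(truth_lm, n_classes = 7L) {
  V <- length(truth_lm)
  counts <- tabulate(as.integer(truth_lm) + 1L, nbins = n_classes)
  w <- 1 - counts / V
  names(w) <- as.character(seq_len(n_classes) - 1L)
  w
}

#' Class-balanced weighted categorical cross-entropy landmark loss
#'
#' \deqn{L_L = -\sum_k w_k \sum_{j \in Y_k} \log P(l_j = k)} with the
#' class-balancing weights of [landmark_weights()]. Probabilities are clamped
#' from below so the loss stays finite.
#'
#' @param prob 4D array `(nx, ny, nz, K)` of per-voxel landmark-class
#'   probabilities.
#' @param truth_lm integer array of 0-based landmark labels.
#' @param weights optional precomputed weights; defaults to
#'   [landmark_weights()] of `truth_lm`.
#' @param clamp lower probability clamp.
#' @return scalar loss (0 for a perfectly confident correct prediction).
#' @export
landmark_loss <- function(prob, truth_lm, weights = NULL, clamp = 1e-12) {
  dp <- dim(prob)
  if (length(dp) != 4L || !identical(dp[1:3], dim(truth_lm)[1:3]))
    stop_bivseg("probability map and truth lattices do not match",
                "bivseg_shape_error")
  K <- dp[4]
  if (is.null(weights)) weights <- landmark_weights(truth_lm, K)
  V <- prod(dp[1:3])
  Pm <- matrix(prob, V, K)
  p_true <- pmax(Pm[cbind(seq_len(V), as.integer(truth_lm) + 1L)], clamp)
  -sum(weights[as.integer(truth_lm) + 1L] * log(p_true))
}

#' Combined multi-task training objective
#'
#' `L = L_D + alpha * L_L + beta * ||W||_F^2`: segmentation Dice loss plus the
#' weighted landmark loss plus weight decay, with `alpha`, `beta` balancing
#' the three terms.
#'
#' @param seg_loss,lm_loss the two task losses.
#' @param weights_norm squared Frobenius norm of all network weights.
#' @param alpha,beta non-negative balance coefficients.
#' @return scalar total loss.
#' @export
total_loss <- function(seg_loss, lm_loss, weights_norm = 0, alpha = 1,
                       beta = 1e-4) {
  stopifnot(alpha >= 0, beta >= 0)
  seg_loss + alpha * lm_loss + beta * weights_norm
}

#' Rasterise a landmark set onto a grid
#'
#' Each landmark is represented by a single foreground voxel carrying its
#' class code (I..VI -> 1..6) on a background of zeros; an optional cubic
#' dilation radius thickens each landmark for training.
#'
#' @param lm a [landmark_set()].
#' @param ref a [cmr_volume()] or [cmr_labelmap()] supplying the lattice.
#' @param dilate integer dilation radius in voxels (default 0: exactly one
#'   voxel per landmark).
#' @return integer array with values in 0..6.
#' @export
rasterise_landmarks <- function(lm, ref, dilate = 0L) {
  d <- dim(ref$data)
  out <- array(0L, d)
  nms <- rownames(lm$voxel)
  codes <- match(nms, landmark_names())
  for (i in seq_along(nms)) {
    v <- lm$voxel[i, ] + 1L
    if (any(v < 1L) || any(v > d)) next
    if (dilate > 0L) {
      xr <- max(1L, v[1] - dilate):min(d[1], v[1] + dilate)
      yr <- max(1L, v[2] - dilate):min(d[2], v[2] + dilate)
      zr <- max(1L, v[3] - dilate):min(d[3], v[3] + dilate)
      out[xr, yr, zr] <- codes[i]
    } else {
      out[v[1], v[2], v[3]] <- codes[i]
    }
  }
  out
}
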