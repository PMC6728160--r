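#' Network configuration for the 2.5D multi-task FCN
#'
#' The network treats a 3D short-axis volume as a multi-channel 2D image whose
#' channels are the slices (a 2.5D representation): all convolutions are
#' in-plane, so the parameter count is independent of the in-plane grid size
#' while every prediction still sees the whole slice stack. Features are
#' learned fine-to-coarse over `length(widths)` scales (2x average pooling
#' between scales), upsampled back to full resolution, concatenated, and fed
#' to two 1x1-convolution softmax heads that emit per-voxel distributions over
#' the `n_seg_classes` tissue classes and the `n_lm_classes` landmark classes.
#'
#' @param in_slices number of short-axis slices (input channels).
#' @param n_seg_classes segmentation classes including background (default 5).
#' @param n_lm_classes landmark classes including background (default 7).
#' @param widths feature maps per scale (fine to coarse).
#' @param convs_per_scale number of 3x3 convolution layers per scale; total
#'   convolutional depth is `sum(convs_per_scale) + 2` (the two heads) and
#'   must be at least 3.
#' @param alpha,beta loss balance: landmark-loss weight and weight decay.
#' @param dice_variant `"global"` (single quotient over all classes and
#'   voxels) or `"per_class"` (one quotient per class, summed), which weights
#'   all tissue classes equally and trains faster when the background
#'   dominates the volume.
#' @param eps Dice-loss smoothing constant.
#' @param clamp log-probability clamp in the landmark loss.
#' @param optimiser `"sgd"` (plain stochastic gradient descent with
#'   momentum, the default) or `"adam"` (per-parameter adaptive steps, useful
#'   for short CPU training runs where SGD converges too slowly).
#' @param lr,momentum,epochs optimiser settings (momentum applies to SGD).
#' @param lr_drop_at,lr_drop_factor fraction of epochs after which the
#'   learning rate is multiplied by the factor.
#' @param augment_prob probability of applying the on-the-fly 3D augmentation
#'   to a training sample.
#' @param augment_args list of range arguments passed to [augment()].
#' @param dilate_lm dilation radius for rasterised training landmarks.
#' @param rng_seed integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @return A `net_config` list.
#' @export
net_config <- function(in_slices, n_seg_classes = 5L, n_lm_classes = 7L,
                       widths = c(32L, 64L, 128L), convs_per_scale = c(4L, 4L, 5L),
                       alpha = 1, beta = 1e-4, dice_variant = c("global", "per_class"),
                       eps = 1e-5, clamp = 1e-12,
                       optimiser = c("sgd", "adam"),
                       lr = 0.05, momentum = 0.9, epochs = 50L,
                       lr_drop_at = 0.7, lr_drop_factor = 0.3,
                       augment_prob = 0.5, augment_args = list(),
                       dilate_lm = 0L, rng_seed = 1L) {
  stopifnot(length(widths) == length(convs_per_scale), alpha >= 0, beta >= 0,
            eps > 0)
  dice_variant <- match.arg(dice_variant)
  optimiser <- match.arg(optimiser)
  conv_layers <- sum(convs_per_scale) + 2L
  if (conv_layers < 3L) stop("need at least 3 convolutional layers")
  structure(list(in_slices = as.integer(in_slices),
                 n_seg_classes = as.integer(n_seg_classes),
                 n_lm_classes = as.integer(n_lm_classes),
                 widths = as.integer(widths),
                 convs_per_scale = as.integer(convs_per_scale),
                 conv_layers = conv_layers,
                 alpha = alpha, beta = beta, dice_variant = dice_variant,
                 eps = eps, clamp = clamp, optimiser = optimiser,
                 lr = lr, momentum = momentum, epochs = as.integer(epochs),
                 lr_drop_at = lr_drop_at, lr_drop_factor = lr_drop_factor,
                 augment_prob = augment_prob, augment_args = augment_args,
                 dilate_lm = as.integer(dilate_lm),
                 rng_seed = as.integer(rng_seed)),
            class = "net_config")
}

#' Compact configuration for desk-scale experiments
#'
#' A small instance of the same architecture (two scales, narrow feature
#' maps) suitable for CPU training on phantom cohorts.
#'
#' @param in_slices number of slices.
#' @param ... overrides passed to [net_config()].
#' @return A `net_config`.
#' @export
tiny_net_config <- function(in_slices, ...) {
  args <- modifyList(list(in_slices = in_slices, widths = c(16L, 24L),
                          convs_per_scale = c(2L, 2L), epochs = 48L,
                          optimiser = "adam", lr = 5e-3,
                          dice_variant = "per_class", dilate_lm = 1L,
                          augment_args = list(trans_range = 4, rot_range = 8)),
                     list(...))
  do.call(net_config, args)
}

new_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(W = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Build (initialise) the multi-task network
#'
#' @param cfg a [net_config()].
#' @return An `sslln_model` with randomly initialised weights (He
#'   initialisation, deterministic per `cfg$rng_seed`).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  n_scales <- length(cfg$widths)
  with_seed(cfg$rng_seed, {
    layers <- list()
    cin <- cfg$in_slices
    for (s in seq_len(n_scales)) {
      for (l in seq_len(cfg$convs_per_scale[s])) {
        layers[[length(layers) + 1L]] <- c(new_conv(3L, 3L, cin, cfg$widths[s]),
                                           list(scale = s))
        cin <- cfg$widths[s]
      }
    }
    # the raw slice channels join the multi-scale concatenation, so each
    # per-slice head output retains direct access to its own slice
    cat_c <- cfg$in_slices + sum(cfg$widths)
    model <- list(cfg = cfg, layers = layers,
                  head_seg = new_conv(1L, 1L, cat_c, cfg$in_slices * cfg$n_seg_classes),
                  head_lm = new_conv(1L, 1L, cat_c, cfg$in_slices * cfg$n_lm_classes))
    class(model) <- "sslln_model"
    model
  })
}

#' @export
print.sslln_model <- function(x, ...) {
  cat(sprintf("<sslln_model> %d conv layers, scales (%s), %d slices, %d+%d classes\n",
              x$cfg$conv_layers, paste(x$cfg$widths, collapse = ", "),
              x$cfg$in_slices, x$cfg$n_seg_classes, x$cfg$n_lm_classes))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass; X is (H, W, S). Returns logits of both heads, and, when
# cache = TRUE, the intermediate activations needed for backpropagation.
sslln_forward <- function(model, X, cache = FALSE) {
  cfg <- model$cfg
  n_scales <- length(cfg$widths)
  H <- dim(X)[1]; W <- dim(X)[2]
  if ((H %% 2^(n_scales - 1)) || (W %% 2^(n_scales - 1)))
    stop("in-plane dims must be divisible by 2^(n_scales - 1)")
  inputs <- list(); acts <- list()
  scale_out <- vector("list", n_scales)
  cur <- X
  li <- 0L
  for (s in seq_len(n_scales)) {
    for (l in seq_len(cfg$convs_per_scale[s])) {
      li <- li + 1L
      lay <- model$layers[[li]]
      dc <- dim(cur)
      if (cache) inputs[[li]] <- cur
      z <- cpp_conv2d_fwd(cur, lay$W, lay$b, dc[1], dc[2], dc[3],
                          dim(lay$W)[4], 3L, 3L)
      cur <- relu(z)
      if (cache) acts[[li]] <- cur
    }
    scale_out[[s]] <- cur
    if (s < n_scales) {
      dc <- dim(cur)
      cur <- cpp_avgpool2_fwd(cur, dc[1], dc[2], dc[3])
    }
  }
  ups <- lapply(seq_len(n_scales), function(s) {
    if (s == 1L) scale_out[[s]]
    else {
      dc <- dim(scale_out[[s]])
      cpp_upsample2_fwd(scale_out[[s]], dc[1], dc[2], dc[3], 2L^(s - 1L))
    }
  })
  cat_c <- cfg$in_slices + sum(cfg$widths)
  concat <- array(c(as.numeric(X), unlist(ups, use.names = FALSE)),
                  c(H, W, cat_c))
  # 1x1 head convolutions are matrix products: (H*W, C) %*% (C, Cout) + bias
  cm <- matrix(concat, H * W, cat_c)
  head_mm <- function(head, cout) {
    out <- cm %*% matrix(head$W, cat_c, cout)
    out <- sweep(out, 2L, head$b, "+")
    array(out, c(H, W, cout))
  }
  seg <- head_mm(model$head_seg, cfg$in_slices * cfg$n_seg_classes)
  lm <- head_mm(model$head_lm, cfg$in_slices * cfg$n_lm_classes)
  out <- list(seg = seg, lm = lm)
  if (cache)
    out$cache <- list(inputs = inputs, acts = acts, scale_out = scale_out,
                      concat = concat, H = H, W = W)
  out
}

# Backward pass: dseg/dlm are gradients on the head logits; returns gradients
# for every parameter in model order.
sslln_backward <- function(model, fwd, dseg, dlm) {
  cfg <- model$cfg
  n_scales <- length(cfg$widths)
  ca <- fwd$cache
  H <- ca$H; W <- ca$W
  cat_c <- cfg$in_slices + sum(cfg$widths)
  cm <- matrix(ca$concat, H * W, cat_c)
  head_bwd <- function(head, dY, cout) {
    dm <- matrix(dY, H * W, cout)
    list(dW = array(crossprod(cm, dm), c(1L, 1L, cat_c, cout)),
         db = colSums(dm),
         dX = dm %*% t(matrix(head$W, cat_c, cout)))
  }
  gs <- head_bwd(model$head_seg, dseg, cfg$in_slices * cfg$n_seg_classes)
  gl <- head_bwd(model$head_lm, dlm, cfg$in_slices * cfg$n_lm_classes)
  dconcat <- array(gs$dX + gl$dX, c(H, W, cat_c))
  grads <- list(layers = vector("list", length(model$layers)),
                head_seg = list(dW = gs$dW, db = gs$db),
                head_lm = list(dW = gl$dW, db = gl$db))
  # split concat gradient per scale (skipping the raw-input block, which
  # needs no parameter gradients) and undo the upsampling
  offs <- cfg$in_slices + c(0L, cumsum(cfg$widths))
  dscale <- vector("list", n_scales)
  dcm <- array(dconcat, c(H * W, cat_c))
  for (s in seq_len(n_scales)) {
    part <- array(dcm[, (offs[s] + 1L):offs[s + 1L]], c(H, W, cfg$widths[s]))
    if (s > 1L) {
      f <- 2L^(s - 1L)
      part <- cpp_upsample2_bwd(part, H %/% f, W %/% f, cfg$widths[s], f)
    }
    dscale[[s]] <- part
  }
  layer_of_scale <- split(seq_along(model$layers),
                          vapply(model$layers, `[[`, 1L, "scale"))
  dnext <- NULL
  for (s in rev(seq_len(n_scales))) {
    d <- dscale[[s]]
    if (s < n_scales) {
      dd <- dim(ca$scale_out[[s]])
      d <- d + cpp_avgpool2_bwd(dnext, dd[1], dd[2], dd[3])
    }
    for (li in rev(layer_of_scale[[as.character(s)]])) {
      d <- d * (fwd$cache$acts[[li]] > 0)
      din <- ca$inputs[[li]]
      dc <- dim(din)
      res <- cpp_conv2d_bwd(din, model$layers[[li]]$W, d, dc[1], dc[2], dc[3],
                            dim(model$layers[[li]]$W)[4], 3L, 3L)
      grads$layers[[li]] <- list(dW = res$dW, db = res$db)
      d <- res$dX
    }
    dnext <- d
  }
  grads
}

weights_sq_norm <- function(model) {
  s <- sum(model$head_seg$W^2) + sum(model$head_lm$W^2)
  for (lay in model$layers) s <- s + sum(lay$W^2)
  s
}

#' Train the multi-task network with stochastic gradient descent
#'
#' Minimises the combined objective (Dice segmentation loss + alpha x
#' class-balanced landmark loss + beta x weight decay) by plain SGD with
#' momentum, one sample per step, applying the 3D on-the-fly augmentation of
#' [augment()] with probability `cfg$augment_prob`. Deterministic for a fixed
#' `cfg$rng_seed`.
#'
#' @param model an `sslln_model` from [build_network()].
#' @param dataset list of training samples, each a list with `volume`
#'   (preprocessed [cmr_volume()]), `labels` ([cmr_labelmap()]) and
#'   `landmarks` ([landmark_set()]).
#' @param epochs optional override of `cfg$epochs`.
#' @param verbose print a loss line per epoch.
#' @return The trained model, with a `log` attribute (data.frame of step,
#'   dice loss, landmark loss and total loss).
#' @export
train_sslln <- function(model, dataset, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sslln_model"), length(dataset) >= 1L)
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  K_s <- cfg$n_seg_classes
  K_l <- cfg$n_lm_classes
  zero_like <- function(l) list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  vel <- list(layers = lapply(model$layers, zero_like),
              head_seg = zero_like(model$head_seg),
              head_lm = zero_like(model$head_lm))
  if (identical(cfg$optimiser, "adam"))
    vel2 <- vel  # second-moment accumulators
  log_rows <- vector("list", epochs * length(dataset))
  step <- 0L
  for (ep in seq_len(epochs)) {
    lr <- cfg$lr * if (ep > cfg$lr_drop_at * epochs) cfg$lr_drop_factor else 1
    ord <- with_seed(derive_seed(cfg$rng_seed, 7000 + ep),
                     sample.int(length(dataset)))
    for (si in ord) {
      step <- step + 1L
      smp <- dataset[[si]]
      vol <- smp$volume; lab <- smp$labels; lmk <- smp$landmarks
      aug_seed <- derive_seed(cfg$rng_seed, step)
      do_aug <- with_seed(aug_seed, runif(1)) < cfg$augment_prob
      if (do_aug) {
        a <- do.call(augment, c(list(v = vol, lab = lab, lm = lmk,
                                     rng_seed = derive_seed(aug_seed, 1)),
                                cfg$augment_args))
        vol <- a$volume; lab <- a$labels; lmk <- a$landmarks
      }
      d <- dim(vol$data)
      truth_seg <- as.integer(lab$data)
      truth_lm <- as.integer(rasterise_landmarks(lmk, lab, cfg$dilate_lm))
      wts <- landmark_weights(truth_lm, K_l)
      fwd <- sslln_forward(model, vol$data, cache = TRUE)
      segr <- if (identical(cfg$dice_variant, "per_class"))
        cpp_seg_dice_loss_perclass(fwd$seg, truth_seg, d[1], d[2], d[3], K_s,
                                   cfg$eps, TRUE)
      else
        cpp_seg_dice_loss(fwd$seg, truth_seg, d[1], d[2], d[3], K_s,
                          cfg$eps, TRUE)
      lmr <- cpp_lm_ce_loss(fwd$lm, truth_lm, d[1], d[2], d[3], K_l,
                            as.numeric(wts), cfg$clamp, TRUE)
      tot <- total_loss(segr$loss, lmr$loss, weights_sq_norm(model),
                        cfg$alpha, cfg$beta)
      if (!is.finite(tot))
        stop_bivseg(sprintf("training diverged (non-finite loss) at step %d", step),
                    "bivseg_training_error")
      grads <- sslln_backward(model, fwd, segr$dlogits,
                              cfg$alpha * lmr$dlogits)
      if (identical(cfg$optimiser, "adam")) {
        b1 <- 0.9; b2 <- 0.999
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        upd <- function(p, v, v2, g) {
          gW <- g$dW + 2 * cfg$beta * p$W
          v$W <- b1 * v$W + (1 - b1) * gW
          v2$W <- b2 * v2$W + (1 - b2) * gW^2
          p$W <- p$W - lr * (v$W / c1) / (sqrt(v2$W / c2) + 1e-8)
          v$b <- b1 * v$b + (1 - b1) * g$db
          v2$b <- b2 * v2$b + (1 - b2) * g$db^2
          p$b <- p$b - lr * (v$b / c1) / (sqrt(v2$b / c2) + 1e-8)
          list(p = p, v = v, v2 = v2)
        }
        for (li in seq_along(model$layers)) {
          r <- upd(model$layers[[li]], vel$layers[[li]], vel2$layers[[li]],
                   grads$layers[[li]])
          model$layers[[li]][c("W", "b")] <- r$p[c("W", "b")]
          vel$layers[[li]] <- r$v; vel2$layers[[li]] <- r$v2
        }
        r <- upd(model$head_seg, vel$head_seg, vel2$head_seg, grads$head_seg)
        model$head_seg <- r$p; vel$head_seg <- r$v; vel2$head_seg <- r$v2
        r <- upd(model$head_lm, vel$head_lm, vel2$head_lm, grads$head_lm)
        model$head_lm <- r$p; vel$head_lm <- r$v; vel2$head_lm <- r$v2
      } else {
        upd <- function(p, v, g) {
          v$W <- cfg$momentum * v$W - lr * (g$dW + 2 * cfg$beta * p$W)
          v$b <- cfg$momentum * v$b - lr * g$db
          p$W <- p$W + v$W
          p$b <- p$b + v$b
          list(p = p, v = v)
        }
        for (li in seq_along(model$layers)) {
          r <- upd(model$layers[[li]], vel$layers[[li]], grads$layers[[li]])
          model$layers[[li]][c("W", "b")] <- r$p[c("W", "b")]
          vel$layers[[li]] <- r$v
        }
        r <- upd(model$head_seg, vel$head_seg, grads$head_seg)
        model$head_seg <- r$p; vel$head_seg <- r$v
        r <- upd(model$head_lm, vel$head_lm, grads$head_lm)
        model$head_lm <- r$p; vel$head_lm <- r$v
      }
      log_rows[[step]] <- data.frame(step = step, epoch = ep,
                                     dice_loss = segr$loss, lm_loss = lmr$loss,
                                     total = tot)
    }
    if (verbose) {
      last <- log_rows[[step]]
      message(sprintf("epoch %d: L_D %.4f, L_L %.4f, total %.4f",
                      ep, last$dice_loss, last$lm_loss, last$total))
    }
  }
  attr(model, "log") <- do.call(rbind, log_rows)
  model
}

# argmax over rows with ties resolved towards the lower (background-favouring)
# class index; returns 0-based classes
argmax_lowest <- function(m) max.col(m, ties.method = "first") - 1L

softmax_probs <- function(logits, H, W, K, S) {
  arr <- array(logits, c(H, W, K, S))
  m <- matrix(aperm(arr, c(1, 2, 4, 3)), H * W * S, K)
  m <- exp(m - apply(m, 1L, max))
  m <- m / rowSums(m)
  m
}

#' Deploy the network on a preprocessed volume
#'
#' Runs the forward pass and decodes both heads: labels and landmark classes
#' are the per-voxel argmax of the probability maps along the class direction
#' (ties broken towards the lower class index, i.e. favouring background),
#' and the landmark set is extracted from the landmark label map with
#' [extract_landmarks()].
#'
#' @param model a trained `sslln_model`.
#' @param v a preprocessed [cmr_volume()] whose slice count equals
#'   `cfg$in_slices`.
#' @return list with `labels` ([cmr_labelmap()]), `landmarks`
#'   ([landmark_set()]), and `prob` (list of two 4D arrays `seg` and `lm`).
#' @export
predict_sslln <- function(model, v) {
  stopifnot(inherits(model, "sslln_model"), inherits(v, "cmr_volume"))
  cfg <- model$cfg
  d <- dim(v$data)
  if (d[3] != cfg$in_slices)
    stop_bivseg(sprintf("volume has %d slices but the network expects %d",
                        d[3], cfg$in_slices), "bivseg_config_error")
  fwd <- sslln_forward(model, v$data, cache = FALSE)
  ps <- softmax_probs(fwd$seg, d[1], d[2], cfg$n_seg_classes, d[3])
  pl <- softmax_probs(fwd$lm, d[1], d[2], cfg$n_lm_classes, d[3])
  seg_lab <- array(argmax_lowest(ps), d)
  lm_lab <- array(argmax_lowest(pl), d)
  labels <- cmr_labelmap(seg_lab, v$spacing, v$origin, v$axes,
                         n_classes = cfg$n_seg_classes)
  lms <- extract_landmarks(lm_lab, labels)
  list(labels = labels, landmarks = lms,
       prob = list(seg = array(ps, c(d, cfg$n_seg_classes)),
                   lm = array(pl, c(d, cfg$n_lm_classes))))
}

#' Extract single-voxel landmarks from a landmark label map
#'
#' For each landmark class the centre of gravity of the largest 26-connected
#' component of that class is taken: the voxel field is the rounded mean
#' position and the world field the exact mean mapped to mm. Classes with no
#' voxels are reported absent.
#'
#' @param lm_labels integer array with values 0..6 (0 = background).
#' @param ref [cmr_volume()] or [cmr_labelmap()] supplying lattice metadata.
#' @return A [landmark_set()] with the landmarks that were found.
#' @export
extract_landmarks <- function(lm_labels, ref) {
  if (inherits(lm_labels, "cmr_labelmap")) lm_labels <- lm_labels$data
  d <- dim(lm_labels)
  vox <- NULL; wrld <- NULL; nms <- character()
  for (k in 1:6) {
    mask <- lm_labels == k
    if (!any(mask)) next
    comps <- cpp_label_components(mask, d, 26L)
    tab <- tabulate(comps[comps > 0L])
    best <- which.max(tab)
    idx <- which(comps == best, arr.ind = TRUE) - 1
    ctr <- colMeans(idx)
    nms <- c(nms, landmark_names()[k])
    vox <- rbind(vox, round(ctr))
    wrld <- rbind(wrld, vox2world(ref, matrix(ctr, 1L)))
  }
  if (is.null(vox)) {
    vox <- matrix(integer(), 0L, 3L)
    wrld <- matrix(numeric(), 0L, 3L)
  }
  rownames(vox) <- rownames(wrld) <- nms
  landmark_set(vox, wrld)
}
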