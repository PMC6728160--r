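test_that("the network builds, emits per-voxel distributions and is 2.5D", {
  cfg <- net_config(in_slices = 4L, widths = c(6L, 8L), convs_per_scale = c(1L, 2L),
                    rng_seed = 2)
  expect_equal(cfg$conv_layers, 5L)
  model <- build_network(cfg)
  X <- with_seed(5, array(runif(16 * 16 * 4), c(16L, 16L, 4L)))
  fwd <- bivseg:::sslln_forward(model, X)
  expect_identical(dim(fwd$seg), c(16L, 16L, 20L))   # N_r per voxel per slice
  expect_identical(dim(fwd$lm), c(16L, 16L, 28L))
  ps <- bivseg:::softmax_probs(fwd$seg, 16L, 16L, 5L, 4L)
  expect_true(all(abs(rowSums(ps) - 1) < 1e-5))
  expect_true(all(ps >= 0))
  # parameter count is independent of the in-plane size
  X2 <- with_seed(6, array(runif(32 * 32 * 4), c(32L, 32L, 4L)))
  fwd2 <- bivseg:::sslln_forward(model, X2)
  expect_identical(dim(fwd2$seg), c(32L, 32L, 20L))
  expect_error(net_config(in_slices = 4L, widths = 4L, convs_per_scale = 0L),
               "at least 3")
})

test_that("backpropagation matches finite differences end to end", {
  H <- 8L; W <- 8L; S <- 4L
  cfg <- net_config(in_slices = S, widths = c(4L, 6L), convs_per_scale = c(1L, 1L),
                    dice_variant = "per_class", rng_seed = 3)
  model <- build_network(cfg)
  X <- with_seed(9, array(runif(H * W * S), c(H, W, S)))
  tr_seg <- with_seed(10, array(sample(0:4, H * W * S, TRUE), c(H, W, S)))
  tr_lm <- array(0L, c(H, W, S)); tr_lm[3, 4, 2] <- 2L; tr_lm[6, 2, 3] <- 5L
  wts <- landmark_weights(tr_lm, 7)
  loss_of <- function(m) {
    fwd <- bivseg:::sslln_forward(m, X, cache = TRUE)
    segr <- bivseg:::cpp_seg_dice_loss_perclass(fwd$seg, as.integer(tr_seg),
                                                H, W, S, 5L, 1e-5, TRUE)
    lmr <- bivseg:::cpp_lm_ce_loss(fwd$lm, as.integer(tr_lm), H, W, S, 7L,
                                   as.numeric(wts), 1e-12, TRUE)
    list(loss = segr$loss + lmr$loss, fwd = fwd, segr = segr, lmr = lmr)
  }
  r <- loss_of(model)
  grads <- bivseg:::sslln_backward(model, r$fwd, r$segr$dlogits, r$lmr$dlogits)
  h <- 1e-6
  probes <- with_seed(11, list(
    list(w = "layers", i = 1L, idx = sample(length(model$layers[[1]]$W), 3)),
    list(w = "head_seg", idx = sample(length(model$head_seg$W), 3)),
    list(w = "head_lm", idx = sample(length(model$head_lm$W), 3))))
  for (pb in probes) {
    for (ix in pb$idx) {
      m2 <- model
      if (pb$w == "layers") {
        m2$layers[[pb$i]]$W[ix] <- m2$layers[[pb$i]]$W[ix] + h
        ga <- grads$layers[[pb$i]]$dW[ix]
      } else {
        m2[[pb$w]]$W[ix] <- m2[[pb$w]]$W[ix] + h
        ga <- grads[[pb$w]]$dW[ix]
      }
      gn <- (loss_of(m2)$loss - r$loss) / h
      expect_lt(abs(gn - ga) / max(abs(gn), 1e-6), 1e-3)
    }
  }
})

test_that("prediction is translation-equivariant away from borders", {
  cfg <- net_config(in_slices = 4L, widths = c(6L, 8L), convs_per_scale = c(1L, 1L),
                    rng_seed = 8)
  model <- build_network(cfg)
  X <- with_seed(12, array(runif(32 * 32 * 4), c(32L, 32L, 4L)))
  sh <- 8L
  Xs <- array(0, dim(X))
  Xs[(sh + 1):32, , ] <- X[1:(32 - sh), , ]
  f1 <- bivseg:::sslln_forward(model, X)
  f2 <- bivseg:::sslln_forward(model, Xs)
  inner <- (sh + 8):(32 - 8)
  expect_equal(f2$seg[inner + 0, 9:24, ], f1$seg[inner - sh, 9:24, ],
               tolerance = 1e-8)
})

test_that("landmark extraction takes the largest component's centroid", {
  g <- array(0L, c(20L, 20L, 8L))
  g[10, 10, 5] <- 5L                     # single-voxel apex class
  g[3:5, 3:5, 2] <- 1L                   # 3x3x1 cluster centred at (3,3,1) 0-based
  g[15:16, 15, 7] <- 1L; g[15, 16, 7] <- 1L   # smaller second component (3 vox)
  ref <- cmr_labelmap(array(0L, dim(g)), c(1, 1, 1))
  lm <- extract_landmarks(g, ref)
  expect_setequal(rownames(lm$voxel), c("I", "V"))
  expect_equal(unname(lm$voxel["V", ]), c(9, 9, 4))
  expect_equal(unname(lm$voxel["I", ]), c(3, 3, 1))
  expect_equal(unname(lm$world["I", ]), c(3, 3, 1))
  # two components of sizes 5 and 2: centroid of the larger one
  g2 <- array(0L, c(10L, 10L, 4L))
  g2[2:6, 2, 2] <- 2L
  g2[9, 9:10, 4] <- 2L
  lm2 <- extract_landmarks(g2, ref = cmr_labelmap(array(0L, dim(g2)), c(1, 1, 1)))
  expect_equal(unname(lm2$voxel["II", ]), c(3, 1, 1))
})

test_that("training descends, is seed-deterministic and flags divergence", {
  coh <- make_cohort(3, rng_seed = 77)
  nz <- dim(coh[[1]]$volume$data)[3]
  pspec <- preproc_spec(target_dims = dim(coh[[1]]$volume$data))
  ds <- lapply(coh, function(p) list(volume = preprocess(p$volume, pspec),
                                     labels = p$labels, landmarks = p$landmarks))
  cfg <- tiny_net_config(in_slices = nz, widths = c(6L, 8L), epochs = 4L,
                         rng_seed = 5)
  m1 <- train_sslln(build_network(cfg), ds)
  log1 <- attr(m1, "log")
  expect_lt(mean(tail(log1$total, 3)), mean(head(log1$total, 3)))
  m2 <- train_sslln(build_network(cfg), ds)
  expect_identical(tail(attr(m2, "log")$total, 1), tail(log1$total, 1))
  # a pathological learning rate raises a training error with the step index
  bad <- tiny_net_config(in_slices = nz, widths = c(6L, 8L), epochs = 3L,
                         optimiser = "sgd", lr = 1e4, rng_seed = 5)
  expect_error(train_sslln(build_network(bad), ds),
               "step", class = "bivseg_training_error")
})

test_that("decoding breaks probability ties towards the lower class", {
  m <- matrix(0.2, 4, 5)          # exact five-way ties
  m[2, 3] <- 0.9                  # unique winner
  m[3, 4] <- m[3, 2] <- 0.5       # two-way tie between classes 1 and 3
  expect_identical(bivseg:::argmax_lowest(m), c(0L, 2L, 1L, 0L))
})
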