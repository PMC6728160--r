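# Independent scalar-loop oracles for the two training losses, written
# directly from their printed forms.
oracle_dice <- function(prob, truth, eps = 1e-5) {
  d <- dim(prob)
  K <- d[4]
  num <- 0; den <- 0
  for (k in 0:(K - 1))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      ind <- as.numeric(truth[i, j, l] == k)
      p <- prob[i, j, l, k + 1]
      num <- num + ind * p
      den <- den + ind^2 + p^2 + eps
    }
  -2 * num / den
}

oracle_lm <- function(prob, truth, w) {
  d <- dim(prob)
  K <- d[4]
  loss <- 0
  for (k in 0:(K - 1)) {
    idx <- which(truth == k, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    s <- 0
    for (r in seq_len(nrow(idx)))
      s <- s + log(prob[idx[r, 1], idx[r, 2], idx[r, 3], k + 1])
    loss <- loss - w[k + 1] * s
  }
  unname(loss)
}

random_prob <- function(d, K, seed) {
  with_seed(seed, {
    p <- array(runif(prod(d) * K, 0.01, 1), c(d, K))
    p / array(rep(apply(p, 1:3, sum), K), c(d, K))
  })
}

test_that("dice_loss matches the scalar-loop oracle on random grids", {
  d <- c(8L, 8L, 4L)
  for (seed in 1:3) {
    pr <- random_prob(d, 5L, seed)
    tr <- with_seed(seed + 50, array(sample(0:4, prod(d), TRUE), d))
    expect_equal(dice_loss(pr, tr), oracle_dice(pr, tr), tolerance = 1e-6)
  }
  # uniform prediction on a 4x4x4 grid, checked against the same oracle
  du <- c(4L, 4L, 4L)
  pu <- array(1 / 5, c(du, 5L))
  tu <- with_seed(4, array(sample(0:4, prod(du), TRUE), du))
  expect_equal(dice_loss(pu, tu), oracle_dice(pu, tu), tolerance = 1e-10)
})

test_that("dice_loss limits: perfect one-hot -> ~-1; disjoint one-hot -> 0", {
  d <- c(6L, 6L, 3L)
  tr <- with_seed(2, array(sample(0:4, prod(d), TRUE), d))
  onehot <- array(0, c(d, 5L))
  V <- prod(d)
  idx <- cbind(which(array(TRUE, d)), as.integer(tr) + 1L)
  Pm <- matrix(0, V, 5L); Pm[idx] <- 1
  onehot <- array(Pm, c(d, 5L))
  eps <- 1e-5
  expect_equal(dice_loss(onehot, tr, eps), -2 * V / (2 * V + eps * V * 5),
               tolerance = 1e-12)
  expect_gt(dice_loss(onehot, tr, eps), -1)
  # shift every predicted class by one: zero agreement
  wrong <- array(Pm[, c(2:5, 1)], c(d, 5L))
  expect_equal(dice_loss(wrong, tr, eps), 0, tolerance = 1e-12)
})

test_that("dice_loss analytic gradient matches finite differences", {
  d <- c(4L, 4L, 2L)
  pr <- random_prob(d, 5L, 7)
  tr <- with_seed(8, array(sample(0:4, prod(d), TRUE), d))
  g <- dice_loss_grad(pr, tr)
  h <- 1e-6
  for (probe in list(c(1, 2, 1, 3), c(4, 4, 2, 1), c(2, 3, 2, 5))) {
    p2 <- pr
    p2[probe[1], probe[2], probe[3], probe[4]] <-
      p2[probe[1], probe[2], probe[3], probe[4]] + h
    num <- (dice_loss(p2, tr) - dice_loss(pr, tr)) / h
    expect_equal(num, g[probe[1], probe[2], probe[3], probe[4]],
                 tolerance = 1e-4)
  }
})

test_that("landmark weights equal 1 - |Y_k|/|Y| exactly, including at full scale", {
  # full 192x192x80 rasterisation: 6 single-voxel landmarks + background
  V <- 192 * 192 * 80
  counts <- c(V - 6, rep(1, 6))
  w <- 1 - counts / V
  expect_identical(V, 2949120)
  expect_equal(w[2], 1 - 1 / 2949120)
  expect_equal(w[1], 6 / 2949120)
  # computed from an actual grid (smaller, same formula)
  tr <- array(0L, c(24L, 24L, 10L))
  tr[5, 5, 2] <- 1L; tr[20, 8, 3] <- 2L; tr[12, 12, 5] <- 3L
  tr[8, 19, 6] <- 4L; tr[15, 4, 8] <- 5L; tr[10, 21, 9] <- 6L
  ww <- landmark_weights(tr, 7L)
  Vt <- length(tr)
  expect_equal(unname(ww), c(1 - (Vt - 6) / Vt, rep(1 - 1 / Vt, 6)))
})

test_that("landmark_loss matches the oracle and its perfect limit is 0", {
  d <- c(8L, 8L, 4L)
  tr <- array(0L, d)
  tr[2, 3, 1] <- 1L; tr[5, 6, 2] <- 4L; tr[7, 1, 3] <- 6L
  pr <- random_prob(d, 7L, 9)
  w <- landmark_weights(tr, 7L)
  expect_equal(landmark_loss(pr, tr), oracle_lm(pr, tr, w), tolerance = 1e-6)
  # perfectly confident correct prediction
  V <- prod(d)
  Pm <- matrix(0, V, 7L)
  Pm[cbind(seq_len(V), as.integer(tr) + 1L)] <- 1
  expect_equal(landmark_loss(array(Pm, c(d, 7L)), tr), 0)
  # zero probability at a truth voxel is clamped, never NaN
  Pz <- random_prob(d, 7L, 10)
  Pz[2, 3, 1, 2] <- 0
  expect_true(is.finite(landmark_loss(Pz, tr)))
})

test_that("total_loss combines the three terms linearly", {
  expect_equal(total_loss(-0.8, 5, 2, alpha = 0, beta = 0), -0.8)
  expect_equal(total_loss(-0.8, 5, 0, alpha = 1, beta = 0), 4.2)
  base <- total_loss(-0.5, 3, 10, alpha = 1, beta = 1e-4)
  twice <- total_loss(-0.5, 3, 10, alpha = 2, beta = 1e-4)
  expect_equal(twice - base, 3)
})

test_that("the training kernels agree with the R-level losses", {
  H <- 6L; W <- 6L; S <- 4L
  logits <- with_seed(3, array(rnorm(H * W * S * 5), c(H, W, 5L * S)))
  tr <- with_seed(4, array(sample(0:4, H * W * S, TRUE), c(H, W, S)))
  res <- bivseg:::cpp_seg_dice_loss(logits, as.integer(tr), H, W, S, 5L, 1e-5, TRUE)
  P <- aperm(array(res$prob, c(H, W, 5L, S)), c(1, 2, 4, 3))
  expect_equal(res$loss, dice_loss(P, tr), tolerance = 1e-10)
  resc <- bivseg:::cpp_seg_dice_loss_perclass(logits, as.integer(tr), H, W, S,
                                              5L, 1e-5, FALSE)
  expect_equal(resc$loss, dice_loss(P, tr, per_class = TRUE), tolerance = 1e-10)
  lml <- with_seed(5, array(rnorm(H * W * S * 7), c(H, W, 7L * S)))
  trl <- array(0L, c(H, W, S)); trl[3, 3, 2] <- 2L; trl[5, 1, 4] <- 6L
  wts <- landmark_weights(trl, 7L)
  resl <- bivseg:::cpp_lm_ce_loss(lml, as.integer(trl), H, W, S, 7L,
                                  as.numeric(wts), 1e-12, FALSE)
  Pl <- aperm(array(resl$prob, c(H, W, 7L, S)), c(1, 2, 4, 3))
  expect_equal(resl$loss, landmark_loss(Pl, trl, wts), tolerance = 1e-10)
})

test_that("rasterisation places one voxel per landmark and dilates on demand", {
  ph <- default_phantom()
  g <- rasterise_landmarks(ph$landmarks, ph$labels)
  expect_identical(sum(g > 0L), 6L)
  expect_setequal(unique(as.integer(g)), 0:6)
  g1 <- rasterise_landmarks(ph$landmarks, ph$labels, dilate = 1L)
  expect_gt(sum(g1 == 3L), 1L)
})
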