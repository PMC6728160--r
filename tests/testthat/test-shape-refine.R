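# Exhaustive quadruple-loop oracle for the non-local fusion rule, mirroring
# the documented patch normalisation and tie-breaking.
fuse_oracle <- function(target, vols, labs, K, pr, wr, h) {
  d <- dim(target)
  out <- array(0L, d)
  pd2 <- function(f, fn, x, y) {
    acc <- 0; nv <- 0
    for (ox in -pr:pr) for (oy in -pr:pr) for (oz in -pr:pr) {
      a <- x + c(ox, oy, oz); b <- y + c(ox, oy, oz)
      if (any(a < 1) || any(a > d) || any(b < 1) || any(b > d)) next
      acc <- acc + (f[a[1], a[2], a[3]] - fn[b[1], b[2], b[3]])^2
      nv <- nv + 1
    }
    acc * (2 * pr + 1)^3 / nv
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    votes <- numeric(K)
    for (n in seq_along(vols))
      for (ox in -wr:wr) for (oy in -wr:wr) for (oz in -wr:wr) {
        y <- c(i + ox, j + oy, k + oz)
        if (any(y < 1) || any(y > d)) next
        w <- exp(-pd2(target, vols[[n]], c(i, j, k), y) / h)
        lab <- labs[[n]][y[1], y[2], y[3]]
        votes[lab + 1] <- votes[lab + 1] + w
      }
    out[i, j, k] <- which.max(votes) - 1L
  }
  out
}

test_that("affine_from_landmarks recovers exact affines and flags degeneracy", {
  src <- tiny_points(1)
  A <- diag(c(1.2, 0.9, 1.1)); tt <- c(3, -2, 5)
  dst <- sweep(src %*% t(A), 2, tt, "+")
  rownames(dst) <- rownames(src)
  tr <- affine_from_landmarks(src, dst)
  expect_lt(max(abs(tr$A - A)), 1e-8)
  expect_lt(max(abs(tr$t - tt)), 1e-8)
  expect_lt(attr(tr, "residual"), 1e-16)
  # identity on itself
  tr0 <- affine_from_landmarks(src, src)
  expect_lt(max(abs(tr0$A - diag(3))), 1e-10)
  # degenerate configurations
  expect_error(affine_from_landmarks(src[1:3, ], dst[1:3, ]),
               class = "bivseg_degeneracy_error")
  flat <- src; flat[, 3] <- 0
  expect_error(affine_from_landmarks(flat, flat),
               class = "bivseg_degeneracy_error")
})

test_that("affine recovery degrades gracefully under landmark noise", {
  src <- tiny_points(2, scale = 30)
  A <- diag(c(1.1, 0.95, 1.05)); tt <- c(2, 1, -3)
  res_all <- with_seed(123, replicate(100, {
    noise <- matrix(rnorm(18, 0, 1), 6, 3)
    dst <- sweep(src %*% t(A), 2, tt, "+") + noise
    rownames(dst) <- rownames(src)
    tr <- affine_from_landmarks(src, dst)
    c(attr(tr, "residual"), max(abs(tr$A - A)))
  }))
  # the residual of a 12-dof fit to 6 noisy points has expectation 6*sd^2:
  # (18 - 12) / 18 of the noise variance survives in-sample
  expect_lt(mean(res_all[1, ]), 1.5 * 6)
  expect_gt(mean(res_all[1, ]), 0.5 * 6)
  expect_lt(mean(res_all[2, ]), 0.2)
})

test_that("label consistency counts agreeing voxels over the overlap", {
  a <- tiny_labelmap(c(4L, 4L, 1L), seed = 6)
  expect_equal(label_consistency(a, a), 1)
  flip <- cmr_labelmap((a$data + 1L) %% 5L, a$spacing)
  expect_equal(label_consistency(a, flip), 0)
  # hand-counted toy pair: 10 of 16 voxels agree
  x <- array(0L, c(4L, 4L, 1L))
  y <- x
  y[1:6] <- 1L
  expect_equal(label_consistency(cmr_labelmap(x, c(1, 1, 1)),
                                 cmr_labelmap(y, c(1, 1, 1))), 10 / 16)
  expect_error(label_consistency(a, tiny_labelmap(c(5L, 4L, 1L))),
               class = "bivseg_shape_error")
})

test_that("atlas selection ranks by NMI with the target's twin first", {
  coh <- make_cohort(6, rng_seed = 31)
  bank <- build_atlas_bank(coh)
  target <- coh[[4]]
  sel <- select_atlases(target$labels, bank, target$landmarks, L = 3L)
  expect_length(sel, 3L)
  expect_equal(sel[[1]]$atlas$id, "subject004")
  expect_equal(sel[[1]]$nmi, 2, tolerance = 1e-10)
  expect_true(all(diff(vapply(sel, `[[`, 0, "nmi")) <= 0))
  expect_warning(all_sel <- select_atlases(target$labels, bank,
                                           target$landmarks, L = 10L),
                 "bank size")
  expect_length(all_sel, 6L)
})

test_that("fuse_labels matches the exhaustive oracle bit-exactly", {
  d <- c(6L, 6L, 4L)
  for (seed in 1:5) {
    dat <- with_seed(seed, list(
      target = array(runif(prod(d)), d),
      vols = lapply(1:3, function(i) array(runif(prod(d)), d)),
      labs = lapply(1:3, function(i) array(sample(0:4, prod(d), TRUE), d))))
    spec <- fusion_spec(patch_radius = 1L, window_radius = 1L, h = 0.7, L = 3L)
    tv <- cmr_volume(dat$target, c(1, 1, 1))
    warped <- lapply(1:3, function(i)
      list(volume = cmr_volume(dat$vols[[i]], c(1, 1, 1)),
           labels = cmr_labelmap(dat$labs[[i]], c(1, 1, 1))))
    fused <- fuse_labels(tv, warped, spec)
    expect_identical(fused$data,
                     fuse_oracle(dat$target, dat$vols, dat$labs, 5L, 1L, 1L, 0.7))
  }
})

test_that("fusion limits: self-atlas identity and h -> Inf majority vote", {
  d <- c(6L, 6L, 4L)
  target <- with_seed(5, array(runif(prod(d)), d))
  lab <- with_seed(6, array(sample(0:4, prod(d), TRUE), d))
  tv <- cmr_volume(target, c(1, 1, 1))
  # one atlas equal to the target, window radius 0: exact copy
  fused <- fuse_labels(tv, list(list(volume = tv,
                                     labels = cmr_labelmap(lab, c(1, 1, 1)))),
                       fusion_spec(patch_radius = 1L, window_radius = 0L, h = 1))
  expect_identical(fused$data, lab)
  # h -> Inf: plain majority vote over atlases and window
  labs <- with_seed(7, lapply(1:3, function(i)
    array(sample(0:2, prod(d), TRUE), d)))
  warped <- lapply(labs, function(l)
    list(volume = cmr_volume(with_seed(8, array(runif(prod(d)), d)), c(1, 1, 1)),
         labels = cmr_labelmap(l, c(1, 1, 1), n_classes = 3L)))
  fused2 <- fuse_labels(tv, warped, fusion_spec(1L, 1L, h = 1e12))
  maj <- array(0L, d)
  unique_maj <- array(TRUE, d)
  for (i in 1:6) for (j in 1:6) for (k in 1:4) {
    counts <- numeric(3)
    for (l in labs) for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      y <- c(i + ox, j + oy, k + oz)
      if (any(y < 1) || any(y > d)) next
      counts[l[y[1], y[2], y[3]] + 1] <- counts[l[y[1], y[2], y[3]] + 1] + 1
    }
    maj[i, j, k] <- which.max(counts) - 1L
    unique_maj[i, j, k] <- sum(counts == max(counts)) == 1L
  }
  # where the majority is unique the h -> Inf fusion must agree with it
  # (exact count ties are legitimately broken by the vanishing weights)
  expect_identical(fused2$data[unique_maj], maj[unique_maj])
  expect_gt(mean(unique_maj), 0.8)
  # no label invention: every fused label was voted somewhere in the window
  expect_true(all(fused2$data %in% 0:2))
  expect_error(fuse_labels(tv, list()), "empty")
})

test_that("FFD registration recovers a known synthetic deformation", {
  ph <- make_phantom(compact_spec(rng_seed = 5))
  lab <- ph$labels
  d <- dim(lab$data)
  delta <- 20 / lab$spacing
  nc <- as.integer(floor((d - 1) / delta) + 4L)
  coef <- with_seed(3, array(rnorm(prod(nc) * 3, 0, 3), c(nc, 3)))
  disp <- bivseg:::cpp_ffd_eval_dense(as.numeric(coef), nc, delta, d)
  moving <- cmr_labelmap(
    array(bivseg:::cpp_warp_disp(as.numeric(lab$data), d, diag(3), c(0, 0, 0),
                                 as.numeric(disp), d, TRUE, 0), d), lab$spacing)
  baseline <- dice(moving, lab, 1L)   # 0-iteration baseline
  ffd <- register_ffd(lab, moving)
  recovered <- warp_ffd(moving, ffd, lab)
  expect_gt(dice(recovered, lab, 1L), baseline)
  expect_gte(dice(recovered, lab, 1L), 0.95)
  # surrogate agreement non-decreasing within every level
  for (h in ffd$history) expect_true(all(diff(h) >= 0))
  # hard agreement never ends below the affine-only initialisation
  expect_gte(ffd$agreement["final"], ffd$agreement["initial"])
})

test_that("registering a map onto itself stays near the identity", {
  ph <- make_phantom(compact_spec(rng_seed = 2))
  ffd <- register_ffd(ph$labels, ph$labels, affine_transform())
  expect_lt(max(abs(ffd$disp)), 0.5)
})

test_that("registration is label-permutation covariant", {
  ph <- make_phantom(compact_spec(rng_seed = 8))
  ph2 <- make_phantom(compact_spec(rng_seed = 9, lv_endo_r = 9.5, extent = 48))
  perm <- c(0L, 3L, 4L, 1L, 2L)   # consistent relabelling of both inputs
  pa <- cmr_labelmap(array(perm[ph$labels$data + 1L], dim(ph$labels$data)),
                     ph$labels$spacing)
  pb <- cmr_labelmap(array(perm[ph2$labels$data + 1L], dim(ph2$labels$data)),
                     ph2$labels$spacing)
  f1 <- register_ffd(ph$labels, ph2$labels, max_iter = 20)
  f2 <- register_ffd(pa, pb, max_iter = 20)
  # the objective is permutation-invariant; optimisation trajectories differ
  # only by floating-point summation order, so the recovered displacement
  # fields agree to a small fraction of a voxel
  expect_lt(max(abs(f1$disp - f2$disp)), 0.1)
  w1 <- warp_ffd(ph2$labels, f1, ph$labels)
  w2 <- warp_ffd(pb, f2, pa)
  # hard warped labels agree (up to the permutation) on almost every voxel
  expect_lt(mean(perm[w1$data + 1L] != w2$data), 0.005)
})

test_that("refinement does not degrade a clean target drawn from the bank", {
  coh <- make_cohort(6, rng_seed = 55)
  bank <- build_atlas_bank(coh)
  tgt <- coh[[3]]
  pp <- preprocess(tgt$volume,
                   preproc_spec(target_dims = dim(tgt$volume$data)))
  out <- refine(pp, tgt$labels, tgt$landmarks, bank, fusion_spec(L = 5L),
                reg_args = list(max_iter = 20))
  sc <- attr(out, "scores")
  expect_equal(sc$atlas[1], "subject003")   # the target's own atlas ranks first
  for (k in 1:4) expect_gte(dice(out, tgt$labels, k), 0.95)
})

test_that("atlas selection prefers morphology-matched atlases", {
  healthy <- make_cohort(4, rng_seed = 61)
  diseased <- make_cohort(4, ph_phantom_spec(), rng_seed = 62)
  for (i in seq_along(diseased)) diseased[[i]]$id <- sprintf("ph%03d", i)
  bank <- build_atlas_bank(c(healthy, diseased))
  tgt <- make_cohort(1, ph_phantom_spec(), rng_seed = 63)[[1]]
  sel <- select_atlases(tgt$labels, bank, tgt$landmarks, 5L)
  ids <- vapply(sel, function(e) e$atlas$id, "")
  expect_gte(sum(grepl("^ph", ids)), 3L)
})
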