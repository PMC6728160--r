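test_that("a phantom contains all 5 classes, nested and artefact-free", {
  ph <- default_phantom()
  lab <- ph$labels$data
  expect_setequal(unique(as.integer(lab)), 0:4)
  d <- dim(lab)
  # each ventricular class forms a single 26-connected component
  for (k in 1:4) {
    comps <- bivseg:::cpp_label_components(lab == k, d, 26L)
    expect_equal(max(comps), 1L)
  }
  # LVC enclosed by LVW in-plane: on a mid-cavity slice, rays from the LVC
  # centroid hit LVW before leaving the heart
  zmid <- round(mean(which(apply(lab == 1, 3, any))))
  sl <- lab[, , zmid]
  ctr <- round(colMeans(which(sl == 1, arr.ind = TRUE)))
  for (dir in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    p <- ctr
    seen <- integer()
    while (all(p >= 1 & p <= dim(sl))) {
      seen <- c(seen, sl[p[1], p[2]])
      p <- p + dir
    }
    expect_true(2L %in% seen)
  }
  # smooth along the long axis: adjacent-slice LVC centroid shift < 1 voxel
  zs <- which(apply(lab == 1, 3, any))
  cent <- t(vapply(zs, function(z)
    colMeans(which(lab[, , z] == 1, arr.ind = TRUE)), numeric(2)))
  expect_lt(max(abs(diff(cent))), 1)
})

test_that("zero noise yields one intensity per class; noise is seeded", {
  sp <- phantom_spec(noise_sd = 0)
  ph <- make_phantom(sp)
  for (k in 0:4)
    expect_equal(unique(as.numeric(ph$volume$data[ph$labels$data == k])),
                 sp$intensity_means[k + 1])
  p1 <- make_phantom(phantom_spec(rng_seed = 9))
  p2 <- make_phantom(phantom_spec(rng_seed = 9))
  expect_identical(p1$volume$data, p2$volume$data)
})

test_that("landmarks sit on their anatomical structures", {
  ph <- default_phantom()
  lab <- ph$labels$data
  d <- dim(lab)
  near <- function(nm, classes, r = 1) {
    v <- ph$landmarks$voxel[nm, ] + 1L
    xr <- max(1, v[1] - r):min(d[1], v[1] + r)
    yr <- max(1, v[2] - r):min(d[2], v[2] + r)
    zr <- max(1, v[3] - r):min(d[3], v[3] + r)
    any(lab[xr, yr, zr] %in% classes)
  }
  expect_true(near("V", 2L))        # apex inside the (dilated) LVW support
  expect_true(near("VI", 1L))       # mitral centre in the basal LVC
  expect_true(near("IV", 2L))
  expect_true(near("II", 4L))
  expect_true(near("I", c(2L, 4L)))
  expect_true(near("III", c(2L, 4L)))
  # apex is the most apical landmark, mitral centre the most basal
  expect_lt(ph$landmarks$world["V", 3], min(ph$landmarks$world[c("I", "II", "III", "IV"), 3]))
  expect_gt(ph$landmarks$world["VI", 3], max(ph$landmarks$world[c("I", "II", "III", "IV"), 3]))
})

test_that("landmark placement is exactly equivariant under rigid pose changes", {
  base <- phantom_spec(noise_sd = 0)
  rot <- phantom_spec(noise_sd = 0, rotations_deg = c(4, -3, 10),
                      translations_mm = c(2, -1, 1.5))
  lm0 <- make_phantom(base)$landmarks$world
  lm1 <- make_phantom(rot)$landmarks$world
  pivot <- (base$grid_dims - 1) * base$spacing / 2
  R <- bivseg:::phantom_rotation(rot$rotations_deg)
  expected <- sweep(sweep(lm0, 2, pivot) %*% t(R), 2,
                    pivot + rot$translations_mm, "+")
  expect_equal(lm1, expected, tolerance = 1e-10)
})

test_that("cohorts jitter reproducibly and spread grows with variability", {
  c1 <- make_cohort(3, rng_seed = 5)
  c2 <- make_cohort(3, rng_seed = 5)
  expect_identical(c1[[2]]$labels$data, c2[[2]]$labels$data)
  expect_false(identical(c1[[1]]$labels$data, c1[[2]]$labels$data))
  # zero variability reproduces the base spec
  c0 <- make_cohort(1, variability = 0, rng_seed = 5)
  expect_identical(c0[[1]]$labels$data, default_phantom()$labels$data)
  # landmark spread is monotone in the variability scale
  spread <- function(v) {
    coh <- make_cohort(8, variability = v, rng_seed = 11)
    lms <- vapply(coh, function(p) p$landmarks$world["V", ], numeric(3))
    mean(apply(lms, 1, sd))
  }
  expect_gt(spread(1.5), spread(0.25))
})

test_that("PH-like preset dilates the RV and thickens its wall", {
  ph <- make_phantom(ph_phantom_spec())
  he <- default_phantom()
  counts <- function(x) tabulate(x$labels$data + 1L, 5L)
  expect_gt(counts(ph)[4], counts(he)[4])        # larger RVC
  expect_lt(counts(ph)[2], counts(he)[2])        # compressed LVC
})

test_that("atlas banks validate, append and round-trip", {
  coh <- make_cohort(3, rng_seed = 21)
  bank <- build_atlas_bank(coh)
  expect_length(bank, 3L)
  # dropping a landmark is rejected with subject and landmark named
  broken <- coh
  keep <- setdiff(landmark_names(), "VI")
  broken[[2]]$landmarks <- landmark_set(broken[[2]]$landmarks$voxel[keep, ],
                                        broken[[2]]$landmarks$world[keep, ])
  expect_error(build_atlas_bank(broken), "subject002.*VI")
  dir <- withr::local_tempdir()
  write_atlas_bank(bank, dir)
  bank2 <- read_atlas_bank(dir)
  expect_length(bank2, 3L)
  expect_equal(bank2[[1]]$volume$data, bank[[1]]$volume$data)
  expect_identical(bank2[[3]]$labels$data, bank[[3]]$labels$data)
  expect_identical(bank2[[2]]$landmarks$voxel, bank[[2]]$landmarks$voxel)
})
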