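test_that("NIfTI round trip preserves data bit-exactly and spacing", {
  v <- tiny_volume(c(8L, 8L, 4L), spacing = c(1.25, 1.25, 2.0))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(dim(v2$data), dim(v$data))
  expect_equal(as.numeric(v2$data), as.numeric(v$data), tolerance = 0)
  expect_lt(max(abs(v2$spacing - c(1.25, 1.25, 2.0))), 1e-6)

  lab <- tiny_labelmap(c(6L, 5L, 4L))
  lpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_labelmap(lab, lpath)
  lab2 <- read_labelmap(lpath)
  expect_identical(lab2$data, lab$data)
})

test_that("unreadable files raise a format error naming the path", {
  expect_error(read_volume("/nonexistent/vol.nii.gz"),
               "nonexistent", class = "bivseg_format_error")
})

test_that("landmark sets round-trip through JSON", {
  ph <- default_phantom()
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(ph$landmarks, path)
  lm2 <- read_landmarks(path)
  expect_identical(lm2$voxel, ph$landmarks$voxel)
  expect_equal(lm2$world, ph$landmarks$world)
})

test_that("preprocess pads, clips percentiles and handles degenerate input", {
  spec <- preproc_spec(target_dims = c(32L, 32L, 12L))
  # constant volume maps to 0 everywhere
  vc <- cmr_volume(array(7, c(10L, 10L, 5L)))
  expect_true(all(preprocess(vc, spec)$data == 0))
  # symmetric zero border around a smaller input
  v <- tiny_volume(c(20L, 20L, 8L), seed = 3)
  out <- preprocess(v, spec)
  expect_identical(dim(out$data), c(32L, 32L, 12L))
  expect_true(all(out$data[1:6, , ] == 0))
  expect_true(all(out$data[, 27:32, ] == 0))
  expect_true(all(out$data >= 0 & out$data <= 1))
  # an extreme outlier is clipped to 1 and the percentile maps to 1
  v2 <- v
  q99 <- quantile(v2$data, 0.99, names = FALSE)
  v2$data[1, 1, 1] <- 10 * q99
  out2 <- preprocess(v2, spec)
  expect_equal(max(out2$data), 1)
  q <- quantile(v2$data, c(0.01, 0.99), names = FALSE)
  inner <- out2$data[7:26, 7:26, 3:10]
  expect_true(all(inner[v2$data <= q[1]] == 0))
  expect_true(all(inner[v2$data >= q[2]] == 1))
  # oversized input errors unless centre-crop is opted in
  big <- tiny_volume(c(40L, 40L, 8L), seed = 4)
  expect_error(preprocess(big, spec), class = "bivseg_spec_error")
  cropped <- preprocess(big, preproc_spec(target_dims = c(32L, 32L, 12L),
                                          centre_crop = TRUE))
  expect_identical(dim(cropped$data), c(32L, 32L, 12L))
})

test_that("preprocess is idempotent up to clipping", {
  v <- tiny_volume(c(20L, 20L, 8L), seed = 5)
  spec <- preproc_spec(target_dims = c(24L, 24L, 10L))
  once <- preprocess(v, spec)
  twice <- preprocess(once, preproc_spec(target_dims = c(24L, 24L, 10L)))
  expect_lt(mean(abs(twice$data - once$data)), 0.02)
})

test_that("resample preserves extent, interpolates linearly, keeps labels nearest", {
  v <- tiny_volume(c(16L, 16L, 8L), spacing = c(1, 1, 2))
  same <- resample(v, c(1, 1, 2))
  expect_equal(same$data, v$data)
  # label maps stay closed under resampling
  ph <- default_phantom()
  lr_lab <- resample(ph$labels, c(1.38, 1.38, 10))
  expect_true(all(lr_lab$data %in% 0:4))
  hr_again <- resample(lr_lab, c(1.25, 1.25, 2))
  expect_true(all(hr_again$data %in% 0:4))
  expect_s3_class(hr_again, "cmr_labelmap")
  # world extent preserved to one voxel
  expect_lt(abs(prod(dim(lr_lab$data) * lr_lab$spacing) -
                  prod(dim(ph$labels$data) * ph$labels$spacing)) /
              prod(dim(ph$labels$data) * ph$labels$spacing), 0.25)
  # linear ramp: downsample-then-upsample error bounded by slope * coarse step
  ramp <- cmr_volume(array(rep(seq(0, 1, length.out = 32), times = 8 * 8),
                           c(32L, 8L, 8L)), c(1, 1, 1))
  slope <- 1 / 31
  down <- resample(ramp, c(4, 1, 1))
  up <- resample(down, c(1, 1, 1))
  inner <- up$data[4:28, , ]
  truth <- ramp$data[4:28, , ]
  expect_lt(max(abs(inner - truth)), slope * 4 + 1e-9)
  expect_error(resample(v, c(0, 1, 1)))
})

test_that("augmentation acts consistently on volume, labels and landmarks", {
  ph <- default_phantom()
  idp <- list(trans = c(0, 0), scale = 1, axis = 1L, angle_deg = 0, gain = 1)
  out <- augment(ph$volume, ph$labels, ph$landmarks, params = idp)
  expect_equal(out$volume$data, ph$volume$data)
  expect_identical(out$labels$data, ph$labels$data)
  expect_equal(out$landmarks$world, ph$landmarks$world)
  # pure in-plane translation moves every landmark by exactly (5dx, -3dy, 0)
  tp <- list(trans = c(5, -3), scale = 1, axis = 3L, angle_deg = 0, gain = 1)
  sh <- augment(ph$volume, ph$labels, ph$landmarks, params = tp)
  shift <- sh$landmarks$world - ph$landmarks$world
  expect_equal(shift,
               matrix(rep(c(5 * 1.25, -3 * 1.25, 0), each = 6), 6L, 3L,
                      dimnames = dimnames(shift)))
  # determinism per seed and label closure
  a1 <- augment(ph$volume, ph$labels, ph$landmarks, rng_seed = 77)
  a2 <- augment(ph$volume, ph$labels, ph$landmarks, rng_seed = 77)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$labels$data, a2$labels$data)
  expect_identical(a1$landmarks$voxel, a2$landmarks$voxel)
  expect_true(all(a1$labels$data %in% 0:4))
})

test_that("augmented landmarks stay on their warped structures", {
  ph <- default_phantom()
  for (seed in c(3, 11)) {
    a <- augment(ph$volume, ph$labels, ph$landmarks, rng_seed = seed,
                 trans_range = 4, rot_range = 8)
    lab <- a$labels$data
    d <- dim(lab)
    on_class <- function(nm, classes) {
      v <- a$landmarks$voxel[nm, ] + 1L
      xr <- max(1, v[1] - 1):min(d[1], v[1] + 1)
      yr <- max(1, v[2] - 1):min(d[2], v[2] + 1)
      zr <- max(1, v[3] - 1):min(d[3], v[3] + 1)
      any(lab[xr, yr, zr] %in% classes)
    }
    expect_true(on_class("V", 2L))            # apex on the LV wall
    expect_true(on_class("VI", 1L))           # mitral centre in the LV cavity
    expect_true(on_class("IV", 2L))           # LV lateral wall
    expect_true(on_class("II", 4L))           # RV lateral wall
    expect_true(on_class("I", c(2L, 4L)))     # inserts at the LVW/RVW junction
    expect_true(on_class("III", c(2L, 4L)))
  }
})
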