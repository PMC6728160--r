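#' Synthetic bi-ventricular phantom specification
#'
#' Parameters of the geometric heart phantom used as a stand-in for clinical
#' high-resolution cohorts: the left ventricle is modelled as two coaxial
#' truncated ellipsoids (cavity and wall), the right ventricle as a larger,
#' laterally shifted ellipsoid pair clipped against the LV epicardium, which
#' yields the characteristic crescent-shaped RV in short-axis views. Intensity
#' is piecewise constant per class plus i.i.d. Gaussian noise. All lengths in
#' mm; the default lattice uses the high-resolution acquisition spacing of
#' 1.25 x 1.25 x 2 mm, and the default heart has adult dimensions
#' (apex-to-base extent 75 mm, LV epicardial radius 24 mm), so the relative
#' severity of 10 mm thick-slice artefacts matches clinical acquisitions.
#'
#' @param grid_dims integer length-3 grid size.
#' @param spacing voxel spacing (mm).
#' @param lv_endo_r,lv_epi_r LV endocardial / epicardial in-plane radii (mm);
#'   epi must exceed endo.
#' @param extent apex-to-base distance (mm).
#' @param base_frac basal truncation plane, as a fraction of the epicardial
#'   long semi-axis above the LV centre.
#' @param rv_shift lateral offset of the RV ellipsoid centre from the LV
#'   centre (mm, towards -x).
#' @param rv_r RV endocardial in-plane semi-axes (mm, length 2).
#' @param rvw_thickness RV free-wall thickness (mm); kept thinner than the LV
#'   wall.
#' @param rv_z_frac RV long semi-axis as a fraction of the LV epicardial long
#'   semi-axis.
#' @param rv_z_off basal offset of the RV centre along the long axis (mm).
#' @param lv_center LV centre in world mm, or `NULL` for a default placed so
#'   the heart fits the field of view.
#' @param rotations_deg,translations_mm pose: rotations about the grid axes
#'   (applied about the field-of-view centre) and a world translation.
#' @param intensity_means per-class mean intensities (background, LVC, LVW,
#'   RVC, RVW) on a 0-1 scale, loosely mimicking b-SSFP contrast (bright
#'   blood, darker myocardium).
#' @param noise_sd Gaussian noise standard deviation.
#' @param rng_seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dims = c(64L, 64L, 48L),
                         spacing = c(1.25, 1.25, 2),
                         lv_endo_r = 15, lv_epi_r = 24,
                         extent = 75, base_frac = 0.55,
                         rv_shift = 20.5, rv_r = c(21.5, 17.5),
                         rvw_thickness = 4.5, rv_z_frac = 0.85, rv_z_off = 2,
                         lv_center = NULL,
                         rotations_deg = c(0, 0, 0),
                         translations_mm = c(0, 0, 0),
                         intensity_means = c(0.15, 0.85, 0.4, 0.8, 0.45),
                         noise_sd = 0.04,
                         rng_seed = 1L) {
  if (lv_epi_r <= lv_endo_r) stop("'lv_epi_r' must exceed 'lv_endo_r'")
  if (rvw_thickness >= lv_epi_r - lv_endo_r)
    stop("'rvw_thickness' must be smaller than the LV wall thickness")
  if (length(intensity_means) != 5L) stop("'intensity_means' needs 5 values")
  fov <- (as.integer(grid_dims) - 1) * spacing
  if (is.null(lv_center))
    lv_center <- c(fov[1] / 2 + 0.11 * fov[1], fov[2] / 2,
                   fov[3] / 2 + 0.1 * fov[3])
  structure(list(grid_dims = as.integer(grid_dims), spacing = as.numeric(spacing),
                 lv_endo_r = lv_endo_r, lv_epi_r = lv_epi_r, extent = extent,
                 base_frac = base_frac, rv_shift = rv_shift, rv_r = rv_r,
                 rvw_thickness = rvw_thickness, rv_z_frac = rv_z_frac,
                 rv_z_off = rv_z_off, lv_center = lv_center,
                 rotations_deg = rotations_deg, translations_mm = translations_mm,
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Pulmonary-hypertension-like phantom preset
#'
#' A variant with dilated RV, thickened RV free wall and a compressed LV
#' cavity, emulating the morphological changes of pulmonary hypertension for
#' robustness experiments.
#'
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
ph_phantom_spec <- function(...) {
  phantom_spec(lv_endo_r = 12.5, lv_epi_r = 22, rv_r = c(23, 19),
               rv_shift = 19, rvw_thickness = 5.5, rv_z_frac = 0.92, ...)
}

phantom_rotation <- function(rot_deg) {
  th <- rot_deg * pi / 180
  rot1 <- function(ax, a) {
    R <- diag(3)
    idx <- setdiff(1:3, ax)
    R[idx, idx] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    R
  }
  rot1(3L, th[3]) %*% rot1(2L, th[2]) %*% rot1(1L, th[1])
}

phantom_geometry <- function(spec) {
  zs_epi <- spec$extent / (1 + spec$base_frac)
  wall <- spec$lv_epi_r - spec$lv_endo_r
  list(
    zs_epi = zs_epi,
    zs_endo = zs_epi - wall,
    z_base = spec$lv_center[3] + spec$base_frac * zs_epi,
    z_apex = spec$lv_center[3] - zs_epi,
    rv_center = spec$lv_center + c(-spec$rv_shift, 0, spec$rv_z_off),
    rv_zs = spec$rv_z_frac * zs_epi,
    wall = wall)
}

# Canonical-frame landmark positions derived analytically from the geometry.
phantom_landmarks_canonical <- function(spec) {
  g <- phantom_geometry(spec)
  cc <- spec$lv_center
  rc <- g$rv_center
  th <- spec$rvw_thickness
  # apex: mid-wall at the most apical LV point
  apex <- c(cc[1], cc[2], cc[3] - (g$zs_epi + g$zs_endo) / 2)
  # mitral valve centre: LVC centroid just below the basal cut
  mitral <- c(cc[1], cc[2], g$z_base - 2)
  # LV lateral-wall mid-point on the mid-ventricular slice (away from the RV)
  lv_lat <- c(cc[1] + (spec$lv_endo_r + spec$lv_epi_r) / 2, cc[2], cc[3])
  # RV lateral-wall turning point: mid-wall at the RV extreme on the mid slice
  zr <- (cc[3] - rc[3])
  s_en <- sqrt(max(0, 1 - (zr / g$rv_zs)^2))
  s_ep <- sqrt(max(0, 1 - (zr / (g$rv_zs + th))^2))
  rv_turn <- c(rc[1] - (spec$rv_r[1] * s_en + (spec$rv_r[1] + th) * s_ep) / 2,
               rc[2], cc[3])
  # RV insert points: LV-epicardium / RV-endocardium junction on a mid-basal slice
  z_ins <- cc[3] + 0.25 * g$zs_epi
  A <- spec$lv_epi_r * sqrt(max(0, 1 - ((z_ins - cc[3]) / g$zs_epi)^2))
  zrr <- (z_ins - rc[3])
  s_in <- sqrt(max(0, 1 - (zrr / g$rv_zs)^2))
  a3 <- spec$rv_r[1] * s_in
  b3 <- spec$rv_r[2] * s_in
  gfun <- function(theta) {
    p <- c(cc[1] + A * cos(theta), cc[2] + A * sin(theta))
    ((p[1] - rc[1]) / a3)^2 + ((p[2] - rc[2]) / b3)^2 - 1
  }
  if (a3 <= 0 || gfun(pi) > 0 || gfun(pi / 2) < 0 || gfun(3 * pi / 2) < 0)
    stop_bivseg("RV/LV geometry does not intersect on the mid-basal slice",
                "bivseg_spec_error")
  th1 <- uniroot(gfun, c(pi / 2, pi), tol = 1e-10)$root
  th2 <- uniroot(gfun, c(pi, 3 * pi / 2), tol = 1e-10)$root
  ins_ant <- c(cc[1] + A * cos(th1), cc[2] + A * sin(th1), z_ins)
  ins_post <- c(cc[1] + A * cos(th2), cc[2] + A * sin(th2), z_ins)
  rbind(I = ins_post, II = rv_turn, III = ins_ant, IV = lv_lat, V = apex,
        VI = mitral)
}

#' Generate one bi-ventricular phantom
#'
#' Builds a label map (background, LVC, LVW, RVC, RVW), a matching noisy
#' intensity volume, and the six anatomical landmarks placed by analytic
#' geometric rules in the phantom's canonical frame and mapped through the
#' pose, which makes landmark placement exactly equivariant under rigid
#' transforms of the pose.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([cmr_volume()]), `labels`
#'   ([cmr_labelmap()]), `landmarks` ([landmark_set()]), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  sp <- spec$spacing
  g <- phantom_geometry(spec)
  fov <- (d - 1) * sp
  pivot <- fov / 2
  R <- phantom_rotation(spec$rotations_deg)
  # world coordinates of all voxels, pulled back to the canonical frame
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  P <- cbind(rep(xs, times = d[2] * d[3]),
             rep(rep(ys, each = d[1]), times = d[3]),
             rep(zs, each = d[1] * d[2]))
  Q <- sweep(sweep(P, 2L, pivot + spec$translations_mm, "-") %*% R, 2L, pivot, "+")
  cc <- spec$lv_center
  rc <- g$rv_center
  thk <- spec$rvw_thickness
  e_endo <- ((Q[, 1] - cc[1]) / spec$lv_endo_r)^2 + ((Q[, 2] - cc[2]) / spec$lv_endo_r)^2 +
    ((Q[, 3] - cc[3]) / g$zs_endo)^2
  e_epi <- ((Q[, 1] - cc[1]) / spec$lv_epi_r)^2 + ((Q[, 2] - cc[2]) / spec$lv_epi_r)^2 +
    ((Q[, 3] - cc[3]) / g$zs_epi)^2
  e_rv <- ((Q[, 1] - rc[1]) / spec$rv_r[1])^2 + ((Q[, 2] - rc[2]) / spec$rv_r[2])^2 +
    ((Q[, 3] - rc[3]) / g$rv_zs)^2
  e_rve <- ((Q[, 1] - rc[1]) / (spec$rv_r[1] + thk))^2 +
    ((Q[, 2] - rc[2]) / (spec$rv_r[2] + thk))^2 +
    ((Q[, 3] - rc[3]) / (g$rv_zs + thk))^2
  below_base <- Q[, 3] <= g$z_base
  lab <- integer(nrow(Q))
  lab[e_rve <= 1 & e_rv > 1 & e_epi > 1] <- 4L
  lab[e_rv <= 1 & e_epi > 1] <- 3L
  lab[e_epi <= 1] <- 2L
  lab[e_endo <= 1] <- 1L
  lab[!below_base] <- 0L
  lab <- array(lab, d)
  if (length(unique(as.integer(lab))) < 5L)
    stop_bivseg("phantom geometry does not produce all 5 classes on this grid",
                "bivseg_spec_error")
  # world-frame apex/base must stay inside the field of view
  lmc <- phantom_landmarks_canonical(spec)
  lmw <- sweep(sweep(lmc, 2L, pivot, "-") %*% t(R), 2L,
               pivot + spec$translations_mm, "+")
  if (any(t(lmw) < 0) || any(t(lmw) > fov))
    stop_bivseg("phantom geometry does not fit the grid", "bivseg_spec_error")
  labels <- cmr_labelmap(lab, sp, c(0, 0, 0), diag(3))
  vol_dat <- array(spec$intensity_means[lab + 1L], d)
  if (spec$noise_sd > 0)
    vol_dat <- vol_dat + with_seed(spec$rng_seed,
                                   array(rnorm(length(vol_dat), 0, spec$noise_sd), d))
  volume <- cmr_volume(vol_dat, sp, c(0, 0, 0), diag(3))
  vox <- round(world2vox(volume, lmw))
  vox <- pmin(pmax(vox, 0), matrix(d - 1L, 6L, 3L, byrow = TRUE))
  rownames(vox) <- rownames(lmw)
  lm <- landmark_set(vox, lmw)
  list(volume = volume, labels = labels, landmarks = lm, spec = spec)
}

#' Generate a cohort of jittered phantoms
#'
#' Draws `n` phantoms whose size, wall thickness, RV geometry, pose and
#' intensities are independently jittered around `base_spec`; `variability`
#' scales all jitter ranges (0 reproduces `base_spec` exactly).
#'
#' @param n number of subjects.
#' @param base_spec a [phantom_spec()].
#' @param variability non-negative scale for all jitter ranges.
#' @param rng_seed integer master seed; each subject derives its own seed.
#' @return list of `n` phantom triples as returned by [make_phantom()].
#' @export
make_cohort <- function(n, base_spec = phantom_spec(), variability = 1,
                        rng_seed = 1L) {
  stopifnot(n >= 1, variability >= 0)
  lapply(seq_len(n), function(i) {
    ph <- NULL
    for (attempt in 0:4) {
      # a draw whose geometry does not fit the grid is redrawn with damped
      # jitter; deterministic given the master seed
      si <- derive_seed(rng_seed, i + 1000 * attempt)
      sp <- cohort_jitter(base_spec, variability * 0.8^attempt, si)
      ph <- tryCatch(make_phantom(sp), bivseg_spec_error = function(e) NULL)
      if (!is.null(ph)) break
    }
    if (is.null(ph)) stop("could not fit a jittered phantom on the grid")
    ph$id <- sprintf("subject%03d", i)
    ph
  })
}

cohort_jitter <- function(base_spec, variability, si) {
    sp <- with_seed(si, {
      v <- variability
      wall <- (base_spec$lv_epi_r - base_spec$lv_endo_r) * runif(1, 1 - 0.12 * v, 1 + 0.12 * v)
      endo <- base_spec$lv_endo_r * runif(1, 1 - 0.1 * v, 1 + 0.1 * v)
      rvt <- base_spec$rvw_thickness * runif(1, 1 - 0.15 * v, 1 + 0.15 * v)
      modifyList(base_spec, list(
        lv_endo_r = endo,
        lv_epi_r = endo + wall,
        extent = base_spec$extent * runif(1, 1 - 0.08 * v, 1 + 0.08 * v),
        rv_r = base_spec$rv_r * runif(2, 1 - 0.08 * v, 1 + 0.08 * v),
        rv_shift = base_spec$rv_shift * runif(1, 1 - 0.06 * v, 1 + 0.06 * v),
        rvw_thickness = min(rvt, 0.8 * wall),
        rotations_deg = runif(3, -5 * v, 5 * v),
        translations_mm = c(runif(2, -3 * v, 3 * v), runif(1, -2 * v, 2 * v)),
        intensity_means = pmin(1, pmax(0.01,
          base_spec$intensity_means + runif(5, -0.02 * v, 0.02 * v))),
        rng_seed = as.integer(si %% 2147483647)))
    })
    class(sp) <- "phantom_spec"
    sp
}
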