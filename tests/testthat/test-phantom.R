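spec32 <- function(...) {
  phantom_spec(matrix_size = 32, fov = 180, n_coils = 1, ...)
}

test_that("cardiac phantom T1s follow fast-exchange mixing per phase", {
  spec <- phantom_spec()
  ed_post <- make_cardiac_phantom(spec, "post", "ED")
  es_post <- make_cardiac_phantom(spec, "post", "ES")
  t1_ed <- unique(ed_post$t1$values[ed_post$myo_mask])
  t1_es <- unique(es_post$t1$values[es_post$myo_mask])
  # more blood at ED shortens post-contrast myocardial T1 relative to ES
  expect_lt(t1_ed, t1_es)
  expect_equal(t1_ed, 957, tolerance = 1e-3)  # calibrated working point
  # pre-contrast: ES and ED myocardial T1 differ by under 2 percent
  ed_pre <- make_cardiac_phantom(spec, "pre", "ED")
  es_pre <- make_cardiac_phantom(spec, "pre", "ES")
  d <- abs(unique(ed_pre$t1$values[ed_pre$myo_mask]) -
             unique(es_pre$t1$values[es_pre$myo_mask]))
  expect_lt(d / unique(ed_pre$t1$values[ed_pre$myo_mask]), 0.02)
  # blood pool carries the contrast-state blood T1
  expect_equal(unique(ed_post$t1$values[ed_post$blood_mask]), 289)
  # equal fractions give identical myocardial T1 at both phases
  eqspec <- phantom_spec(imbv_es = 0.07, imbv_ed = 0.07)
  expect_equal(
    unique(make_cardiac_phantom(eqspec, "post", "ES")$t1$values[
      make_cardiac_phantom(eqspec, "post", "ES")$myo_mask]),
    unique(make_cardiac_phantom(eqspec, "post", "ED")$t1$values[
      make_cardiac_phantom(eqspec, "post", "ED")$myo_mask]))
  # systolic contraction conserves myocardial area (thicker wall)
  expect_equal(spec$r_epi_es^2 - spec$r_endo_es^2,
               spec$r_epi_ed^2 - spec$r_endo_ed^2)
})

test_that("capillary phantom realizes the requested area fractions", {
  ph <- make_capillary_phantom(0.269, 0.155, resolution = 0.05)
  expect_equal(ph$fv_realized[1] / ph$fv_realized[2], 1.73, tolerance = 0.01)
  expect_equal(ph$fv_realized, c(0.269, 0.155), tolerance = 0.01)

  # empty request gives uniform agar
  ph0 <- make_capillary_phantom(0, 0, resolution = 0.1)
  expect_true(all(ph0$labels == 0L))
  expect_equal(unique(as.vector(ph0$t1$values)), 1200)

  # doubling resolution moves realized fractions by < 0.5 percent
  fine <- make_capillary_phantom(0.269, 0.155, resolution = 0.025)
  expect_lt(max(abs(fine$fv_realized - ph$fv_realized) / ph$fv_realized),
            0.005)

  # circle packing beyond the square-lattice bound is rejected
  expect_error(make_capillary_phantom(0.9, 0.1), "packing")
})

test_that("the radial forward model matches the analytic disk transform", {
  n <- 32
  img <- disk_image(n, radius_px = 8)
  ang <- c(0, 33.7, 90, 121.3)
  traj <- t1track:::radial_trajectory(ang, 2 * n)
  kx <- as.vector(traj$kx); ky <- as.vector(traj$ky)
  s <- nudft_forward(kx, ky, img)
  rho <- sqrt(kx^2 + ky^2)
  jinc <- ifelse(rho < 1e-12, pi * 8^2,
                 8 * besselJ(2 * pi * 8 * rho, 1) / rho)
  # the rasterized disk is the continuous disk seen through the square
  # pixel aperture, whose transfer function is separable sinc
  sincf <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  analytic <- jinc * sincf(kx) * sincf(ky)
  expect_lt(sqrt(mean(Mod(s - analytic)^2)) / max(Mod(analytic)), 0.01)
})

test_that("acquisition is linear, seeded, and models in-flow contrast", {
  params <- seq_params()
  timing <- cardiac_timing(100, phase = "ES")

  # forward-model linearity: doubling fractions' phantom signal adds
  sA <- simulate_acquisition(spec32(), params, timing, 20, 3, "post")
  img <- phantom_signal_image(spec32(), params, 20, "ES", "post")
  traj <- list(kx = sA$kx, ky = sA$ky)
  direct <- nudft_forward(as.vector(traj$kx), as.vector(traj$ky),
                          img$values * coil_sensitivity_maps(32, 1, 180)[, , 1])
  expect_equal(as.vector(sA$samples[, , 1]), 2 * direct - direct,
               tolerance = 1e-10)

  # seed determinism: identical spec and seed give identical bytes
  k1 <- simulate_acquisition(spec32(noise_sd = 0.05), params, timing, 20, 2)
  k2 <- simulate_acquisition(spec32(noise_sd = 0.05), params, timing, 20, 2)
  expect_identical(k1$samples, k2$samples)
  k3 <- simulate_acquisition(spec32(noise_sd = 0.05, seed = 9), params,
                             timing, 20, 2)
  expect_false(identical(k1$samples, k3$samples))

  # hybrid mode: dark blood at its SPGR steady state; 2D-only with in-flow:
  # fully recovered spins make blood brighter than steady state
  spec_in <- spec32(inflow = TRUE)
  dark <- phantom_signal_image(spec_in, params, 20, "ES", "post", "hybrid")
  bright <- phantom_signal_image(spec_in, params, 20, "ES", "post", "2d_only")
  bl <- attr(dark, "blood_interior")
  expect_equal(unique(dark$values[bl]),
               spgr_steady_state(289, params$tr, 20)$signal_ss,
               tolerance = 1e-9)
  expect_true(all(bright$values[bl] > dark$values[bl]))
  expect_equal(unique(bright$values[bl]), sin(20 * pi / 180),
               tolerance = 1e-9)
})

test_that("k-space text serialization round-trips", {
  k <- simulate_acquisition(spec32(noise_sd = 0.01), seq_params(),
                            cardiac_timing(90, phase = "ED"), 3, 2, "pre")
  path <- file.path(tempdir(), "kspace_test")
  write_kspace(k, path)
  k2 <- read_kspace(path)
  expect_equal(k2$samples, k$samples, tolerance = 1e-12)
  expect_equal(k2$angles, k$angles)
  expect_equal(k2$phase_label, k$phase_label)
  expect_equal(k2$params$tr, k$params$tr)
})
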