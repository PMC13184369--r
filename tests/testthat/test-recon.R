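smooth_phantom <- function(n) {
  # band-limited test object: sum of Gaussian blobs (negligible energy at
  # the unsampled k-space corners)
  x <- seq_len(n) - 0.5 - n / 2
  xx <- matrix(x, n, n); yy <- t(xx)
  exp(-((xx - 3)^2 + (yy + 2)^2) / (2 * (n / 6)^2)) +
    0.6 * exp(-((xx + n / 5)^2 + (yy - n / 6)^2) / (2 * (n / 12)^2))
}

make_kspace <- function(img, n_proj, n_coils = 1, noise_sd = 0, seed = 1,
                        fov = 180) {
  n <- nrow(img)
  ang <- (seq_len(n_proj) - 1) * tiny_golden_angle(7)
  traj <- t1track:::radial_trajectory(ang, 2 * n)
  sens <- coil_sensitivity_maps(n, n_coils, fov)
  samples <- array(0 + 0i, c(2 * n, n_proj, n_coils))
  for (c in seq_len(n_coils)) {
    samples[, , c] <- nudft_forward(as.vector(traj$kx), as.vector(traj$ky),
                                    img * sens[, , c])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    samples <- samples +
      array(complex(real = rnorm(length(samples), sd = noise_sd),
                    imaginary = rnorm(length(samples), sd = noise_sd)),
            dim(samples))
  }
  structure(list(samples = samples, angles = ang, kx = traj$kx, ky = traj$ky,
                 beat = rep(1L, n_proj), phase_label = rep("ES", n_proj),
                 n = n, fov = fov, params = seq_params(), fa = 20,
                 contrast = "post", mode = "hybrid", noise_sd = noise_sd),
            class = "radial_kspace")
}

test_that("the gridding operator agrees with the exact DFT and its adjoint", {
  set.seed(11)
  n <- 32
  ang <- (0:59) * tiny_golden_angle(7)
  traj <- t1track:::radial_trajectory(ang, 2 * n)
  kx <- as.vector(traj$kx); ky <- as.vector(traj$ky)
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  plan <- nufft_plan(kx, ky, n)

  s_grid <- nufft_forward(plan, img)
  s_dft <- nudft_forward(kx, ky, img)
  expect_lt(sqrt(sum(Mod(s_grid - s_dft)^2) / sum(Mod(s_dft)^2)), 5e-3)

  # the high-accuracy (width 6) plan used for data simulation
  plan6 <- nufft_plan(kx, ky, n, width = 6)
  expect_lt(sqrt(sum(Mod(nufft_forward(plan6, img) - s_dft)^2) /
                   sum(Mod(s_dft)^2)), 1e-4)

  # adjoint identity <A x, y> = <x, A^H y> for random vectors
  y <- complex(real = rnorm(plan$ns), imaginary = rnorm(plan$ns))
  lhs <- sum(Conj(y) * nufft_forward(plan, img))
  rhs <- sum(Conj(nufft_adjoint(plan, y)) * img)
  expect_lt(Mod(lhs - rhs) / (sqrt(sum(Mod(img)^2)) * sqrt(sum(Mod(y)^2))),
            1e-6)

  # batched multi-coil application equals the per-coil loop
  arr <- array(img, c(n, n, 2)); arr[, , 2] <- 2 * img
  multi <- t1track:::nufft_forward_multi(plan, arr)
  expect_equal(multi[, 1], s_grid, tolerance = 1e-12)
  expect_equal(multi[, 2], 2 * s_grid, tolerance = 1e-12)
})

test_that("projection pooling subsets by cardiac phase", {
  k <- make_kspace(smooth_phantom(32), 40)
  expect_equal(dim(pool_projections(k, "ES")$samples), dim(k$samples))
  expect_error(pool_projections(k, "ED"), "no projections")

  k$phase_label <- rep(c("ES", "ED"), 20)
  es <- pool_projections(k, "ES")
  expect_equal(dim(es$samples)[2], 20)
  expect_equal(es$angles, k$angles[k$phase_label == "ES"])

  # 240 beats x 18 projections pooled for one phase
  expect_equal(240 * 18, 4320)
})

test_that("gridded reconstruction localizes, scales linearly, and degrades with undersampling", {
  n <- 32
  # impulse: the PSF peaks at the programmed pixel
  img <- matrix(0, n, n); img[20, 12] <- 1
  k <- make_kspace(img, 60)
  g <- gridded_recon(k)
  expect_equal(which(g$values == max(g$values), arr.ind = TRUE)[1, ],
               c(row = 20, col = 12))

  # fully sampled smooth object: NRMSE under 5%
  ph <- smooth_phantom(n)
  kfull <- make_kspace(ph, ceiling(pi / 2 * n))
  expect_lt(nrmse(gridded_recon(kfull), ph), 0.05)

  # linearity in the data
  g1 <- gridded_recon(kfull)
  k2 <- kfull; k2$samples <- 2 * k2$samples
  expect_equal(gridded_recon(k2)$values, 2 * g1$values, tolerance = 1e-10)

  # streak energy rises monotonically along a subsampling ladder
  errs <- vapply(c(60, 30, 15, 8), function(np) {
    nrmse(gridded_recon(make_kspace(ph, np)), ph)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))

  # voronoi-style weights give a comparable fully-sampled reconstruction
  cfgv <- recon_config(mode = "gridded", density_comp = "voronoi")
  expect_lt(nrmse(gridded_recon(kfull, cfgv), ph), 0.05)
})

test_that("CG-SENSE solves the encoded inverse problem", {
  n <- 32
  ph <- smooth_phantom(n)

  # single uniform coil, fully sampled: SENSE reduces to the inverse
  # transform and agrees with gridding up to the ramp-filter approximation
  # error of the gridded image (a couple of percent)
  k1 <- make_kspace(ph, 120, n_coils = 1)
  sens1 <- coil_sensitivity_maps(n, 1, 180)
  cg1 <- cg_sense_recon(k1, sens1, recon_config(cg_iterations = 25))
  gr1 <- gridded_recon(k1)
  a <- sum(gr1$values * cg1$values) / sum(gr1$values^2)
  expect_lt(sqrt(sum((a * gr1$values - cg1$values)^2) /
                   sum(cg1$values^2)), 0.035)
  # and the CG solution is quantitatively accurate on its own scale
  expect_lt(nrmse(cg1, ph, scale = "none"), 0.01)

  # multi-coil: residuals decrease monotonically and the image is accurate
  k8 <- make_kspace(ph, 120, n_coils = 8)
  sens8 <- coil_sensitivity_maps(n, 8, 180)
  cg8 <- cg_sense_recon(k8, sens8, recon_config(cg_iterations = 25))
  res <- attr(cg8, "residuals")
  expect_true(all(diff(res) < 0))
  expect_lt(nrmse(cg8, ph, scale = "none"), 0.01)
})
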