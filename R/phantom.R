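#' Digital cardiac phantom specification
#'
#' A mid-ventricular short-axis slice: a left-ventricular blood pool inside
#' a myocardial annulus whose T1 follows fast-exchange mixing of the
#' intravascular and extravascular pools, `R1 = f_v R1_blood + (1-f_v) R1_ev`,
#' with the intravascular fraction set per cardiac phase. At end-systole the
#' annulus contracts radially with conserved myocardial cross-section
#' (thicker wall). Defaults encode the implemented study: 1.4 mm pixels
#' (matrix 128 over a 180 mm field of view), blood T1 1820/289 ms pre/post
#' contrast, extravascular T1 such that the post-contrast end-diastolic
#' myocardium sits at 957 ms, fractions 6.2% (ES) / 7.7% (ED), 8 coils.
#'
#' @param matrix_size Image matrix (even).
#' @param fov Field of view (mm).
#' @param r_endo_ed,r_epi_ed End-diastolic endocardial/epicardial radii (mm).
#' @param r_endo_es End-systolic endocardial radius (mm); the epicardial
#'   radius follows from myocardial-area conservation.
#' @param imbv_es,imbv_ed Intravascular fractions at the two phases.
#' @param tissue A [two_compartment_tissue()] template carrying blood and
#'   extravascular T1s and the residence time (its `f_v` is overridden per
#'   phase).
#' @param heart_rate Heart rate (bpm) for acquisition simulation.
#' @param inflow Replace ventricular blood by fully recovered spins when the
#'   sequence runs in 2D-only mode (bright blood).
#' @param noise_sd Complex-Gaussian noise SD per k-space sample component;
#'   alternatively give `snr`.
#' @param snr Image-domain-equivalent signal-to-noise ratio of the
#'   pre-contrast PD-weighted myocardium (used to derive `noise_sd`).
#' @param seed Integer seed for the noise stream.
#' @param n_coils Number of receiver coils.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 128, fov = 180,
                         r_endo_ed = 24, r_epi_ed = 32, r_endo_es = 16,
                         imbv_es = 0.062, imbv_ed = 0.077,
                         tissue = two_compartment_tissue(0.07),
                         heart_rate = 100, inflow = FALSE,
                         noise_sd = 0, snr = NULL, seed = 1L, n_coils = 8) {
  stopifnot(matrix_size %% 2 == 0, fov > 0, r_endo_ed < r_epi_ed,
            r_endo_es <= r_epi_ed, imbv_es > 0, imbv_ed < 1,
            inherits(tissue, "two_compartment_tissue"))
  if (imbv_es > imbv_ed) {
    stop("physiological presets require imbv_es <= imbv_ed")
  }
  r_epi_es <- sqrt(r_endo_es^2 + r_epi_ed^2 - r_endo_ed^2)
  if (r_epi_es > fov / 2) stop("phantom geometry exceeds the field of view")
  structure(list(matrix_size = matrix_size, fov = fov,
                 r_endo_ed = r_endo_ed, r_epi_ed = r_epi_ed,
                 r_endo_es = r_endo_es, r_epi_es = r_epi_es,
                 imbv_es = imbv_es, imbv_ed = imbv_ed, tissue = tissue,
                 heart_rate = heart_rate, inflow = inflow,
                 noise_sd = noise_sd, snr = snr, seed = as.integer(seed),
                 n_coils = n_coils),
            class = "phantom_spec")
}

mixed_t1 <- function(tissue, f_v, contrast) {
  r1b <- 1000 / switch(contrast, pre = tissue$t1_blood_pre,
                       post = tissue$t1_blood_post)
  1000 / (f_v * r1b + (1 - f_v) * (1000 / tissue$t1_ev))
}

phantom_radii <- function(spec, phase) {
  if (phase == "ES") c(endo = spec$r_endo_es, epi = spec$r_epi_es)
  else c(endo = spec$r_endo_ed, epi = spec$r_epi_ed)
}

# label matrix on an optionally supersampled grid: 0 bg, 1 myocardium, 2 blood
phantom_labels <- function(spec, phase, supersample = 1) {
  n <- spec$matrix_size * supersample
  px <- spec$fov / n
  x <- (seq_len(n) - 0.5 - n / 2) * px
  r2 <- outer(x^2, x^2, `+`)
  rad <- phantom_radii(spec, phase)
  lab <- matrix(0L, n, n)
  lab[r2 <= rad["epi"]^2] <- 1L
  lab[r2 <= rad["endo"]^2] <- 2L
  lab
}

#' Build T1 and M0 maps of the cardiac phantom
#'
#' @param spec A [phantom_spec()].
#' @param contrast `"pre"` or `"post"`.
#' @param phase `"ES"` or `"ED"`.
#' @param supersample Integer rasterization refinement (maps are returned on
#'   the refined grid).
#' @return A list with `t1` and `m0` [map_image()]s and logical region masks
#'   `myo_mask`, `blood_mask`.
#' @export
make_cardiac_phantom <- function(spec, contrast = c("pre", "post"),
                                 phase = c("ED", "ES"), supersample = 1) {
  contrast <- match.arg(contrast); phase <- match.arg(phase)
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_labels(spec, phase, supersample)
  f_v <- if (phase == "ES") spec$imbv_es else spec$imbv_ed
  t1_myo <- mixed_t1(spec$tissue, f_v, contrast)
  t1_blood <- switch(contrast, pre = spec$tissue$t1_blood_pre,
                     post = spec$tissue$t1_blood_post)
  t1 <- matrix(0, nrow(lab), ncol(lab))
  t1[lab == 1L] <- t1_myo
  t1[lab == 2L] <- t1_blood
  m0 <- (lab > 0L) * 1
  px <- spec$fov / nrow(lab)
  mask <- lab > 0L
  list(t1 = map_image(t1, px, "ms", mask, phase, contrast),
       m0 = map_image(m0, px, "a.u.", mask, phase, contrast),
       myo_mask = lab == 1L, blood_mask = lab == 2L)
}

box_downsample <- function(m, factor) {
  if (factor == 1) return(m)
  n <- nrow(m) / factor
  a <- array(m, c(factor, n, factor, n))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

#' Shrink a logical mask by one 4-neighborhood layer
#'
#' @param mask Logical matrix.
#' @param iterations Number of erosion passes.
#' @return The eroded logical matrix.
#' @export
erode_mask <- function(mask, iterations = 1) {
  for (i in seq_len(iterations)) {
    n1 <- nrow(mask); n2 <- ncol(mask)
    up <- rbind(mask[-1, ], FALSE); dn <- rbind(FALSE, mask[-n1, ])
    lf <- cbind(mask[, -1], FALSE); rt <- cbind(FALSE, mask[, -n2])
    mask <- mask & up & dn & lf & rt
  }
  mask
}

#' Steady-state signal image of the cardiac phantom
#'
#' Pixelwise SPGR steady-state signal from the phase- and
#' contrast-appropriate T1/M0 maps, rasterized on a supersampled grid and
#' box-averaged to acquisition resolution so that edge pixels carry the
#' partial-volume mixtures an acquisition would see. In `"2d_only"` mode
#' with `inflow = TRUE` the ventricular blood is replaced by fully recovered
#' in-flowing spins (`m0 sin(fa)`, bright blood); in the hybrid mode blood
#' stays at its steady state (dark blood).
#'
#' @param spec A [phantom_spec()].
#' @param params A [seq_params()].
#' @param fa Flip angle of the acquisition (degrees).
#' @inheritParams make_cardiac_phantom
#' @param mode `"hybrid"` or `"2d_only"`.
#' @param supersample Rasterization refinement for the partial-volume model.
#' @return A real [map_image()] at acquisition resolution, with attributes
#'   `myo_interior` and `blood_interior`: full-coverage region masks.
#' @export
phantom_signal_image <- function(spec, params, fa, phase, contrast,
                                 mode = c("hybrid", "2d_only"),
                                 supersample = 4) {
  mode <- match.arg(mode)
  ph <- make_cardiac_phantom(spec, contrast, phase, supersample)
  sig <- matrix(0, nrow(ph$t1$values), ncol(ph$t1$values))
  inside <- ph$t1$mask
  sig[inside] <- ph$m0$values[inside] *
    spgr_steady_state(ph$t1$values[inside], params$tr, fa)$signal_ss
  if (mode == "2d_only" && spec$inflow) {
    sig[ph$blood_mask] <- ph$m0$values[ph$blood_mask] * sin(deg2rad(fa))
  }
  n <- spec$matrix_size
  out <- box_downsample(sig, supersample)
  myo_full <- box_downsample(ph$myo_mask * 1, supersample) >= 1 - 1e-9
  blood_full <- box_downsample(ph$blood_mask * 1, supersample) >= 1 - 1e-9
  res <- map_image(out, spec$fov / n, "a.u.",
                   box_downsample(inside * 1, supersample) > 0.5,
                   phase, contrast)
  attr(res, "myo_interior") <- myo_full
  attr(res, "blood_interior") <- blood_full
  res
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian-lobe magnitude profiles centered on a ring around the object
#' with a smooth linear phase per coil — a deterministic stand-in for a
#' cardiac-torso receiver array. `n_coils = 1` returns a uniform coil.
#'
#' @param n Matrix size.
#' @param n_coils Number of coils.
#' @param fov Field of view (mm).
#' @return Complex array `n x n x n_coils`.
#' @export
coil_sensitivity_maps <- function(n, n_coils = 8, fov = 180) {
  if (n_coils == 1) return(array(1 + 0i, c(n, n, 1)))
  px <- fov / n
  x <- (seq_len(n) - 0.5 - n / 2) * px
  xx <- matrix(x, n, n); yy <- t(xx)
  sens <- array(0 + 0i, c(n, n, n_coils))
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils
    cx <- 0.55 * fov * cos(ang); cy <- 0.55 * fov * sin(ang)
    mag <- exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * (0.45 * fov)^2))
    phs <- 2 * pi * 0.15 * (xx * sin(ang) - yy * cos(ang)) / fov + ang / 3
    sens[, , c] <- mag * exp(1i * phs)
  }
  sens
}

#' Noise level for a target PD-image SNR
#'
#' Converts an image-domain-equivalent SNR (referenced to the mean
#' pre-contrast end-diastolic PD-weighted myocardial signal, unit-transform
#' convention) into a per-sample complex-Gaussian k-space SD.
#'
#' @param spec A [phantom_spec()].
#' @param params A [seq_params()].
#' @param snr Target SNR.
#' @return k-space noise SD.
#' @export
kspace_noise_sd <- function(spec, params, snr) {
  img <- phantom_signal_image(spec, params, params$fa_pd, "ED", "pre")
  myo <- attr(img, "myo_interior")
  mean(img$values[myo]) * spec$matrix_size / snr
}

radial_trajectory <- function(angles_deg, nro) {
  r <- ((seq_len(nro) - 1) - nro / 2) / nro
  th <- angles_deg * pi / 180
  list(kx = outer(r, cos(th)), ky = outer(r, sin(th)))
}

#' Simulate a golden-angle radial acquisition of the cardiac phantom
#'
#' Builds the hybrid 2D/3D schedule, takes the steady-state signal image of
#' the requested phase/contrast, multiplies by coil sensitivities and
#' evaluates the radial k-space samples — by exact discrete Fourier
#' summation for small problems, by high-accuracy gridding NUFFT otherwise —
#' then adds seeded complex Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @param params A [seq_params()].
#' @param timing A [cardiac_timing()] (its phase labels the projections).
#' @param fa Flip angle of this acquisition (degrees).
#' @param total_beats Number of imaged beats.
#' @param contrast `"pre"` or `"post"`.
#' @param mode `"hybrid"` or `"2d_only"`.
#' @param method `"auto"`, `"dft"` (exact) or `"nufft"`.
#' @param seed Noise seed; defaults to `spec$seed`.
#' @param plan Optional precomputed high-accuracy [nufft_plan()] for this
#'   trajectory (reused across the acquisitions of a study).
#' @return An object of class `radial_kspace`: complex `samples`
#'   `[readout x projection x coil]`, per-projection `angles`, `beat` and
#'   `phase_label`, trajectory `kx`/`ky` (cycles/pixel), grid size `n`,
#'   `fov`, the protocol and the noise level used.
#' @export
simulate_acquisition <- function(spec, params, timing, fa, total_beats,
                                 contrast = c("pre", "post"),
                                 mode = c("hybrid", "2d_only"),
                                 method = c("auto", "dft", "nufft"),
                                 seed = NULL, plan = NULL) {
  contrast <- match.arg(contrast); mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(spec, "phantom_spec"))
  sched <- build_schedule(params, timing, total_beats)
  img <- phantom_signal_image(spec, params, fa, timing$phase, contrast, mode)
  n <- spec$matrix_size
  nro <- 2L * n
  traj <- radial_trajectory(sched$angles, nro)
  sens <- coil_sensitivity_maps(n, spec$n_coils, spec$fov)
  ns <- length(traj$kx)
  if (method == "auto") {
    method <- if (ns * as.numeric(n)^2 <= 2e7) "dft" else "nufft"
  }
  if (method == "nufft" && is.null(plan)) {
    plan <- nufft_plan(as.vector(traj$kx), as.vector(traj$ky), n, width = 6)
  }
  samples <- array(0 + 0i, c(nro, length(sched$angles), spec$n_coils))
  if (method == "dft") {
    for (c in seq_len(spec$n_coils)) {
      samples[, , c] <- nudft_forward(as.vector(traj$kx), as.vector(traj$ky),
                                      img$values * sens[, , c])
    }
  } else {
    cims <- array(0 + 0i, c(n, n, spec$n_coils))
    for (c in seq_len(spec$n_coils)) cims[, , c] <- img$values * sens[, , c]
    samples[] <- nufft_forward_multi(plan, cims)
  }
  sd <- spec$noise_sd
  if (!is.null(spec$snr)) sd <- kspace_noise_sd(spec, params, spec$snr)
  if (sd > 0) {
    if (is.null(seed)) seed <- spec$seed
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(length(samples), sd = sd),
              imaginary = stats::rnorm(length(samples), sd = sd))
    })
    samples <- samples + array(noise, dim(samples))
  }
  out <- structure(list(samples = samples, angles = sched$angles,
                        kx = traj$kx, ky = traj$ky,
                        beat = sched$beat,
                        phase_label = rep(timing$phase, length(sched$angles)),
                        n = n, fov = spec$fov, params = params, fa = fa,
                        contrast = contrast, mode = mode, noise_sd = sd),
                   class = "radial_kspace")
  attr(out, "sim_plan") <- plan
  out
}

#' @export
print.radial_kspace <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<radial_kspace> %d readout x %d projections x %d coils (%s, FA %g, %s)\n",
              d[1], d[2], d[3], x$phase_label[1], x$fa, x$contrast))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Capillary fractional-volume phantom
#'
#' A high-resolution label image of a contrast-doped agar block containing
#' two square regions of cylindrical cavities (capillary cross-sections)
#' filled with blood-like solution, packed on square lattices whose pitch is
#' chosen to realize the two requested area fractions. Down-sampled to
#' acquisition resolution the cavities are unresolved and each voxel is a
#' partial-volume intravascular/extravascular mixture.
#'
#' @param fv1,fv2 Requested area fractions of the two regions.
#' @param cavity_diameter Cavity diameter (mm).
#' @param roi_size Side of each square region (mm).
#' @param resolution Rasterization pixel (mm).
#' @param contrast `"pre"` or `"post"`.
#' @param t1_ev Agar (extravascular) T1, ms.
#' @param t1_blood_pre,t1_blood_post Blood-like solution T1 (ms).
#' @return A list with the label matrix (`0` agar, `1`/`2` cavities of the
#'   two regions), the high-resolution `t1` [map_image()], realized area
#'   fractions `fv_realized`, and the two region masks.
#' @export
make_capillary_phantom <- function(fv1 = 0.269, fv2 = 0.155,
                                   cavity_diameter = 0.6, roi_size = 20,
                                   resolution = 0.025,
                                   contrast = c("post", "pre"),
                                   t1_ev = 1200, t1_blood_pre = 1820,
                                   t1_blood_post = 289) {
  contrast <- match.arg(contrast)
  stopifnot(fv1 >= 0, fv2 >= 0, cavity_diameter > 0, resolution > 0)
  if (max(fv1, fv2) >= pi / 4) {
    stop("infeasible packing: square-lattice circle fraction must stay below pi/4")
  }
  margin <- 2
  wx <- 2 * roi_size + 3 * margin
  wy <- roi_size + 2 * margin
  n1 <- round(wx / resolution); n2 <- round(wy / resolution)
  lab <- matrix(0L, n1, n2)
  xc <- (seq_len(n1) - 0.5) * resolution
  yc <- (seq_len(n2) - 0.5) * resolution
  # the analysis ROI is trimmed to an integer number of lattice cells so the
  # periodic unit-cell fraction is realized exactly (up to pixelization)
  roi_side <- function(fv) {
    if (fv == 0) return(roi_size)
    pitch <- cavity_diameter / 2 * sqrt(pi / fv)
    floor(roi_size / pitch) * pitch
  }
  fill_roi <- function(lab, x0, fv, code) {
    if (fv == 0) return(lab)
    pitch <- cavity_diameter / 2 * sqrt(pi / fv)
    ncirc <- floor(roi_size / pitch)
    # per-circle sub-pixel dither (golden-ratio sequence) decorrelates the
    # lattice from the raster grid, so pixel-count errors average out even
    # when the pitch is nearly commensurate with the resolution
    phi <- (sqrt(5) - 1) / 2
    centers_x <- x0 + (seq_len(ncirc) - 0.5) * pitch
    centers_y <- margin + (seq_len(ncirc) - 0.5) * pitch
    ix <- which(xc >= x0 & xc <= x0 + roi_size)
    iy <- which(yc >= margin & yc <= margin + roi_size)
    r2 <- (cavity_diameter / 2)^2
    idx <- 0
    for (cx0 in centers_x) {
      for (cy0 in centers_y) {
        idx <- idx + 1
        cx <- cx0 + ((idx * phi) %% 1 - 0.5) * resolution
        cy <- cy0 + ((idx * phi * phi) %% 1 - 0.5) * resolution
        jx <- ix[abs(xc[ix] - cx) <= cavity_diameter / 2]
        jy <- iy[abs(yc[iy] - cy) <= cavity_diameter / 2]
        d2 <- outer((xc[jx] - cx)^2, (yc[jy] - cy)^2, `+`)
        lab[jx, jy][d2 <= r2] <- code
      }
    }
    lab
  }
  lab <- fill_roi(lab, margin, fv1, 1L)
  lab <- fill_roi(lab, 2 * margin + roi_size, fv2, 2L)
  s1 <- roi_side(fv1); s2 <- roi_side(fv2)
  roi1 <- outer(xc >= margin & xc <= margin + s1,
                yc >= margin & yc <= margin + s1, `&`)
  roi2 <- outer(xc >= 2 * margin + roi_size & xc <= 2 * margin + roi_size + s2,
                yc >= margin & yc <= margin + s2, `&`)
  realized <- c(sum(lab == 1L) / sum(roi1), sum(lab == 2L) / sum(roi2))
  req <- c(fv1, fv2)
  if (any(req > 0 & abs(realized - req) / req > 0.01)) {
    stop(sprintf("realized fractions %.4f/%.4f deviate more than 1%% from request",
                 realized[1], realized[2]))
  }
  t1b <- switch(contrast, pre = t1_blood_pre, post = t1_blood_post)
  t1 <- matrix(t1_ev, n1, n2)
  t1[lab > 0L] <- t1b
  list(labels = lab,
       t1 = map_image(t1, resolution, "ms", contrast = contrast),
       fv_realized = realized, fv_requested = req,
       roi1 = roi1, roi2 = roi2)
}
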