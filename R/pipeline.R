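#' End-to-end pipeline configuration
#'
#' Nested configuration for the synthetic ES/ED blood-volume experiment:
#' sequence protocol, phantom, reconstruction, T1 quantification and run
#' control. Round-trips losslessly through YAML.
#'
#' @param sequence A [seq_params()].
#' @param phantom A [phantom_spec()].
#' @param recon A [recon_config()]. The pipeline default runs CG close to
#'   its residual tolerance (30 iterations) so quantitative maps are not
#'   limited by early stopping.
#' @param total_beats Imaged beats per acquisition (the implemented
#'   protocol's 20-30 s scans at ~100 bpm correspond to about 40 beats).
#' @param lut_grid T1 grid for the look-up table (ms).
#' @param seed Run seed (overrides the phantom seed).
#' @param out_dir Output directory for [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sequence = seq_params(),
                            phantom = phantom_spec(snr = 30),
                            recon = recon_config(cg_iterations = 30),
                            total_beats = 40,
                            lut_grid = seq(100, 3000, by = 2),
                            seed = 1L, out_dir = NULL) {
  structure(list(sequence = sequence, phantom = phantom, recon = recon,
                 total_beats = total_beats, lut_grid = lut_grid,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tis <- do.call(two_compartment_tissue,
                 raw$phantom$tissue[c("f_v", "t1_blood_pre", "t1_blood_post",
                                      "t1_ev", "tau_b", "m0")])
  ph <- raw$phantom
  ph$tissue <- tis
  ph$r_epi_es <- NULL
  pipeline_config(
    sequence = do.call(seq_params, raw$sequence),
    phantom = do.call(phantom_spec,
                      ph[c("matrix_size", "fov", "r_endo_ed", "r_epi_ed",
                           "r_endo_es", "imbv_es", "imbv_ed", "tissue",
                           "heart_rate", "inflow", "noise_sd", "snr", "seed",
                           "n_coils")]),
    recon = do.call(recon_config, raw$recon),
    total_beats = raw$total_beats,
    lut_grid = if (is.null(raw$lut_grid)) seq(100, 3000, 2) else raw$lut_grid,
    seed = raw$seed, out_dir = raw$out_dir)
}

#' Acquire the full synthetic study
#'
#' Simulates the eight acquisitions of the protocol: pre/post contrast x
#' ES/ED phase x PD-weighted (3 deg) / T1-weighted (20 deg), each with its
#' own noise sub-seed derived from the run seed.
#'
#' @param config A [pipeline_config()].
#' @param method Forward-model method passed to [simulate_acquisition()].
#' @return Named list of [radial_kspace] objects
#'   (`pre_ES_pd`, `pre_ES_t1w`, ..., `post_ED_t1w`).
#' @export
acquire_study <- function(config, method = "auto") {
  spec <- config$phantom
  params <- config$sequence
  study <- list()
  i <- 0L
  sim_plan <- NULL
  for (contrast in c("pre", "post")) {
    for (phase in c("ES", "ED")) {
      timing <- cardiac_timing(spec$heart_rate, phase = phase)
      for (wt in c("pd", "t1w")) {
        i <- i + 1L
        fa <- if (wt == "pd") params$fa_pd else params$fa_t1
        k <- simulate_acquisition(spec, params, timing, fa,
                                  config$total_beats, contrast = contrast,
                                  method = method,
                                  seed = config$seed * 131L + i,
                                  plan = sim_plan)
        if (is.null(sim_plan) && !is.null(attr(k, "sim_plan"))) {
          sim_plan <- attr(k, "sim_plan")
        }
        attr(k, "sim_plan") <- NULL
        study[[paste(contrast, phase, wt, sep = "_")]] <- k
      }
    }
  }
  study
}

reconstruct_one <- function(k, config, sens, plan = NULL) {
  if (config$recon$mode == "cg_sense") {
    cg_sense_recon(k, sens, config$recon, plan = plan)
  } else {
    gridded_recon(k, config$recon, plan = plan)
  }
}

#' Reconstruct a study and fit T1 and blood-volume maps
#'
#' Reconstructs the eight acquisitions (sharing one gridding plan — the
#' trajectory repeats), forms per-phase/contrast PD-normalized ratio maps,
#' inverts the look-up table, measures per-phase blood T1s in the
#' blood-pool interior, and maps the blood volume fraction per phase.
#'
#' @param study An [acquire_study()] result.
#' @param config A [pipeline_config()].
#' @param erode Extra erosion depth (pixels) applied to the full-coverage
#'   interior ROIs, guarding region statistics against edge ringing.
#' @return A list with `t1_maps` (per contrast/phase), `imbv` (per-phase
#'   [imbv_map()] results), `blood_t1` (tibble), `rel_change` (tibble from
#'   [relative_es_ed_change()] over the myocardial interior), and `images`.
#' @export
study_maps <- function(study, config, erode = 1) {
  spec <- config$phantom
  params <- config$sequence
  sens <- coil_sensitivity_maps(spec$matrix_size, spec$n_coils, spec$fov)
  plan <- kspace_plan(study[[1]], config$recon)
  images <- lapply(study, reconstruct_one, config = config, sens = sens,
                   plan = plan)
  lut <- build_lut(params, grid = config$lut_grid)
  interior <- function(phase, what) {
    key <- paste(what, phase, erode, spec$matrix_size, spec$fov,
                 spec$r_endo_ed, spec$r_epi_ed, spec$r_endo_es, sep = "|")
    hit <- interior_cache[[key]]
    if (!is.null(hit)) return(hit)
    img <- phantom_signal_image(spec, params, params$fa_pd, phase, "pre")
    out <- erode_mask(attr(img, what), erode)
    interior_cache[[key]] <- out
    out
  }
  t1_maps <- list()
  blood_rows <- list()
  for (contrast in c("pre", "post")) {
    for (phase in c("ES", "ED")) {
      key <- paste(contrast, phase, sep = "_")
      ratio <- normalize_pd(images[[paste0(key, "_t1w")]],
                            images[[paste0(key, "_pd")]])
      t1_maps[[key]] <- fit_t1_map(ratio, lut)
      bl <- interior(phase, "blood_interior")
      blood_rows[[key]] <- tibble::tibble(
        contrast = contrast, phase = phase,
        blood_t1 = stats::median(t1_maps[[key]]$values[bl & t1_maps[[key]]$mask]))
    }
  }
  blood <- do.call(rbind, blood_rows)
  get_blood <- function(contrast, phase) {
    blood$blood_t1[blood$contrast == contrast & blood$phase == phase]
  }
  imbv <- list()
  rois <- list()
  for (phase in c("ES", "ED")) {
    imbv[[phase]] <- imbv_map(t1_maps[[paste0("pre_", phase)]],
                              t1_maps[[paste0("post_", phase)]],
                              get_blood("pre", phase),
                              get_blood("post", phase))
    rois[[phase]] <- list(global = interior(phase, "myo_interior"))
  }
  rel <- relative_es_ed_change(imbv$ES, imbv$ED, rois$ES, rois$ED)
  list(t1_maps = t1_maps, imbv = imbv, blood_t1 = blood,
       rel_change = rel, images = images, myo_rois = rois)
}

# geometry-keyed cache of interior ROI masks (cheap to rebuild, hot in the
# segment-wise repeatability loop)
interior_cache <- new.env(parent = emptyenv())

#' Segment-wise repeatability (coefficient of variation)
#'
#' Retrospectively truncates each acquisition into consecutive,
#' non-overlapping scan segments (by beat), reruns the reconstruction /
#' T1 / blood-volume chain per segment, and reports the coefficient of
#' variation of the relative ES-to-ED change across segments.
#'
#' @param study An [acquire_study()] result.
#' @param config A [pipeline_config()].
#' @param n_segments Number of consecutive segments.
#' @param min_projections Minimum projections per segment per acquisition.
#' @return A list with `cov`, per-segment `rel_change` values, and the
#'   segment beat ranges.
#' @export
repeatability_cov <- function(study, config, n_segments = 3,
                              min_projections = 100) {
  n_beats <- max(study[[1]]$beat)
  bounds <- floor(seq(0, n_beats, length.out = n_segments + 1))
  per_seg <- diff(bounds) * length(unique(study[[1]]$angles)) / n_beats
  npb <- config$sequence$projections_per_beat
  if (any(diff(bounds) * npb < min_projections)) {
    stop(sprintf("too few projections per segment (need >= %d)", min_projections))
  }
  vals <- numeric(n_segments)
  for (s in seq_len(n_segments)) {
    sub <- lapply(study, function(k) {
      sel <- k$beat > bounds[s] & k$beat <= bounds[s + 1]
      k$samples <- k$samples[, sel, , drop = FALSE]
      k$angles <- k$angles[sel]
      k$kx <- k$kx[, sel, drop = FALSE]
      k$ky <- k$ky[, sel, drop = FALSE]
      k$beat <- k$beat[sel]
      k$phase_label <- k$phase_label[sel]
      k
    })
    vals[s] <- study_maps(sub, config)$rel_change$rel_change[1]
  }
  list(cov = stats::sd(vals) / mean(vals), rel_change = vals,
       segment_bounds = bounds)
}

#' Run the end-to-end synthetic pipeline
#'
#' Phantom, eight acquisitions, reconstruction, T1 maps, blood-volume maps,
#' regional statistics and the relative ES-to-ED change; writes NIfTI maps,
#' CSV tables, a JSON summary, the resolved YAML config and a log when
#' `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary` (list), `maps`, `rel_change`,
#'   and the output directory (or `NULL`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  config$phantom$seed <- config$seed
  study <- acquire_study(config)
  res <- study_maps(study, config)
  segs_es <- aha_segments(res$myo_rois$ES$global)
  segs_ed <- aha_segments(res$myo_rois$ED$global)
  seg_tbl <- relative_es_ed_change(res$imbv$ES, res$imbv$ED, segs_es, segs_ed)
  truth <- (config$phantom$imbv_ed - config$phantom$imbv_es) /
    config$phantom$imbv_ed
  summary <- list(
    seed = config$seed,
    programmed_rel_change = truth,
    measured_rel_change = res$rel_change$rel_change[1],
    imbv_es = res$rel_change$imbv_es[1],
    imbv_ed = res$rel_change$imbv_ed[1],
    blood_t1 = as.list(stats::setNames(res$blood_t1$blood_t1,
                                       paste(res$blood_t1$contrast,
                                             res$blood_t1$phase, sep = "_"))))
  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$t1_maps)) {
      write_map_nifti(res$t1_maps[[nm]], file.path(out, paste0("t1_", nm, ".nii")))
    }
    for (ph in names(res$imbv)) {
      write_map_nifti(res$imbv[[ph]]$imbv_map,
                      file.path(out, paste0("imbv_", ph, ".nii")))
    }
    utils::write.csv(rbind(res$rel_change, seg_tbl),
                     file.path(out, "rel_change.csv"), row.names = FALSE)
    utils::write.csv(res$blood_t1, file.path(out, "blood_t1.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = 10)
    write_config(config, file.path(out, "config.yaml"))
    writeLines(sprintf("[%s] pipeline seed=%d beats=%d elapsed=%.1fs",
                       format(Sys.time()), config$seed, config$total_beats,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))),
               file.path(out, "run.log"))
  }
  invisible(list(summary = summary, maps = res, segments = seg_tbl,
                 out_dir = out))
}

#' Regenerate the simulation study tables
#'
#' Recomputes, as tibbles, the package's simulation experiments: the
#' feasible-heart-rate table per flip angle, the cyclic T1-tracking traces,
#' the exchange-regime bias sweep, the slice-profile sensitivity of the
#' estimated fraction, and the fast/no-exchange convergence of
#' fractional-volume estimates with flip angle.
#'
#' @param which Subset of `c("feasible_hr", "tracking", "exchange_bias",
#'   "slice_profile", "convergence")`.
#' @param out_dir Optional directory to write one CSV per table.
#' @return Named list of tibbles.
#' @export
reproduce_figures <- function(which = c("feasible_hr", "tracking",
                                        "exchange_bias", "slice_profile",
                                        "convergence"),
                              out_dir = NULL) {
  which <- match.arg(which, several.ok = TRUE)
  out <- list()
  if ("feasible_hr" %in% which) {
    out$feasible_hr <- feasible_hr_table()
  }
  if ("tracking" %in% which) {
    grids <- expand.grid(fa = c(10, 20), heart_rate = c(50, 100))
    rows <- lapply(seq_len(nrow(grids)), function(i) {
      tr <- track_t1_timeseries(heart_rate = grids$heart_rate[i],
                                fa = grids$fa[i])
      tr$fa <- grids$fa[i]; tr$heart_rate <- grids$heart_rate[i]
      tr
    })
    out$tracking <- do.call(rbind, rows)
  }
  if ("exchange_bias" %in% which) {
    out$exchange_bias <- exchange_bias_table()
  }
  if ("slice_profile" %in% which) {
    out$slice_profile <- slice_profile_sensitivity()
  }
  if ("convergence" %in% which) {
    out$convergence <- fv_convergence_table()
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Slice-profile sensitivity of the fraction estimate
#'
#' For sinc pulses of varying time-bandwidth product, replaces the nominal
#' flip angle by through-slice signal averaging over the simulated
#' excitation profile and reports the resulting bias of the fast-exchange
#' fraction estimate relative to an ideal profile.
#'
#' @param tbws Time-bandwidth products to evaluate.
#' @param fv True intravascular fraction.
#' @param params A [seq_params()].
#' @return A tibble with `tbw`, `fv_est`, `rel_error`.
#' @export
slice_profile_sensitivity <- function(tbws = c(2, 4, 8, 12), fv = 0.077,
                                      params = seq_params()) {
  lut <- build_lut(params)
  tis <- two_compartment_tissue(fv)
  profile_signal <- function(t1, fa_profile, fa_nominal, fa) {
    # through-slice average of the steady-state signal under the profile,
    # with both flip angles scaled by the same local transmit factor
    scale <- fa_profile / fa_nominal
    mean(spgr_steady_state(t1, params$tr, pmin(fa * scale, 179))$signal_ss)
  }
  rows <- lapply(tbws, function(tbw) {
    prof <- simulate_slice_profile(rf_pulse(params$fa_t1, tbw = tbw))
    inside <- abs(prof$position) <= 1.5 * 8     # span of the simulated grid
    fp <- prof$fa[inside]
    t1_app <- function(contrast) {
      t1_tis_true <- mixed_t1(tis, fv, contrast)
      s_hi <- profile_signal(t1_tis_true, fp, params$fa_t1, params$fa_t1)
      s_lo <- profile_signal(t1_tis_true, fp, params$fa_t1, params$fa_pd)
      lut_invert(lut, s_hi / s_lo)
    }
    est <- imbv_fast_exchange(contrast_pair(
      tissue_pre = t1_app("pre"), tissue_post = t1_app("post"),
      blood_pre = tis$t1_blood_pre, blood_post = tis$t1_blood_post))
    tibble::tibble(tbw = tbw, fv_est = est, rel_error = abs(est / fv - 1))
  })
  do.call(rbind, rows)
}

#' Write / read a radial acquisition as plain text
#'
#' Serializes a [radial_kspace] object as a JSON header (angles, labels,
#' protocol, grid) plus a CSV of per-sample real/imaginary parts — a
#' portable text container for the raw data.
#'
#' @param k A `radial_kspace`.
#' @param path Base path (without extension); writes `<path>.json` and
#'   `<path>.csv`.
#' @return `write_kspace` returns `path` invisibly; `read_kspace` the
#'   reconstructed object.
#' @export
write_kspace <- function(k, path) {
  stopifnot(inherits(k, "radial_kspace"))
  hdr <- list(n = k$n, fov = k$fov, fa = k$fa, contrast = k$contrast,
              mode = k$mode, noise_sd = k$noise_sd, dim = dim(k$samples),
              angles = k$angles, beat = k$beat, phase_label = k$phase_label,
              params = unclass(k$params))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(re = as.vector(Re(k$samples)),
                              im = as.vector(Im(k$samples))),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(path, ".csv"))
  samples <- array(complex(real = tab$re, imaginary = tab$im), hdr$dim)
  traj <- radial_trajectory(hdr$angles, hdr$dim[1])
  params <- do.call(seq_params, hdr$params)
  structure(list(samples = samples, angles = hdr$angles, kx = traj$kx,
                 ky = traj$ky, beat = hdr$beat,
                 phase_label = hdr$phase_label, n = hdr$n, fov = hdr$fov,
                 params = params, fa = hdr$fa, contrast = hdr$contrast,
                 mode = hdr$mode, noise_sd = hdr$noise_sd),
            class = "radial_kspace")
}
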