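#' Tiny golden-angle increments
#'
#' The generalized (tiny) golden angles `psi_n = 180 / (phi + n - 1)` with
#' `phi = (1 + sqrt(5)) / 2`. `n = 1` is the classic golden angle modulo
#' 180 degrees (111.25 deg); `n = 7` is the increment used by the hybrid
#' 2D/3D sequence (about 23.63 deg), small enough that consecutive radial
#' readouts make only small eddy-current-inducing jumps while the pooled
#' angles still cover k-space near-uniformly.
#'
#' @param n Index of the tiny golden angle (integer `>= 1`); vectorized.
#' @return Angle increment(s) in degrees.
#' @examples
#' tiny_golden_angle(7) # ~23.63
#' @export
tiny_golden_angle <- function(n = 7) {
  if (any(n < 1) || any(n != round(n))) stop("n must be an integer >= 1")
  phi <- (1 + sqrt(5)) / 2
  180 / (phi + n - 1)
}

#' Sequence protocol parameters
#'
#' Timing and flip-angle plan of the continuous hybrid 2D/3D SPGR sequence.
#' Defaults follow the implemented protocol: TR/TE 4.5/1.7 ms, 3 degree
#' proton-density-weighted and 20 degree T1-weighted flip angles, 18 radial
#' projections per heartbeat (a temporal footprint of 81 ms), a 5 s
#' initialization of continuous slab (3D) pulses, and the tiny golden angle
#' psi_7 as the per-TR angular increment.
#'
#' @param tr Repetition time (ms).
#' @param te Echo time (ms). Enters only through a constant T2* attenuation
#'   that cancels in PD normalization; kept for protocol bookkeeping.
#' @param fa_pd Proton-density-weighted flip angle (degrees).
#' @param fa_t1 T1-weighted flip angle (degrees).
#' @param projections_per_beat Number of 2D readouts per heartbeat (`<= 22`,
#'   so that the imaging window stays under 100 ms at TR 4.5 ms).
#' @param init_duration Duration of the initial continuous 3D drive (ms).
#' @param trigger_delay Delay from the R-wave to the start of the 2D imaging
#'   window (ms); selects the cardiac phase.
#' @param angle_increment Radial angle increment per TR (degrees).
#' @return An object of class `seq_params`.
#' @export
seq_params <- function(tr = 4.5, te = 1.7, fa_pd = 3, fa_t1 = 20,
                       projections_per_beat = 18, init_duration = 5000,
                       trigger_delay = 0,
                       angle_increment = tiny_golden_angle(7)) {
  stopifnot(tr > 0, te > 0, te < tr, fa_pd > 0, fa_t1 > 0,
            projections_per_beat >= 0, projections_per_beat == round(projections_per_beat),
            init_duration >= 0, trigger_delay >= 0, angle_increment > 0)
  if (projections_per_beat > 22) {
    stop("at most 22 projections per beat are allowed (temporal footprint < 100 ms)")
  }
  structure(list(tr = tr, te = te, fa_pd = fa_pd, fa_t1 = fa_t1,
                 projections_per_beat = projections_per_beat,
                 init_duration = init_duration, trigger_delay = trigger_delay,
                 angle_increment = angle_increment),
            class = "seq_params")
}

#' Cardiac timing
#'
#' Either a constant heart rate or an explicit list of R-R intervals, plus
#' the cardiac phase the 2D window targets.
#'
#' @param heart_rate Constant heart rate (bpm); ignored if `rr_intervals`
#'   given.
#' @param rr_intervals Explicit R-R intervals (ms).
#' @param phase Cardiac phase label, `"ES"` or `"ED"`.
#' @return An object of class `cardiac_timing`.
#' @export
cardiac_timing <- function(heart_rate = NULL, rr_intervals = NULL,
                           phase = c("ES", "ED")) {
  phase <- match.arg(phase)
  if (is.null(rr_intervals)) {
    stopifnot(!is.null(heart_rate), heart_rate > 0)
  } else {
    stopifnot(all(rr_intervals > 0))
  }
  structure(list(heart_rate = heart_rate, rr_intervals = rr_intervals,
                 phase = phase), class = "cardiac_timing")
}

rr_of <- function(timing, n_beats) {
  if (!is.null(timing$rr_intervals)) {
    rep_len(timing$rr_intervals, n_beats)
  } else {
    rep(60000 / timing$heart_rate, n_beats)
  }
}

#' Build the hybrid 2D/3D excitation schedule
#'
#' Lays out the continuous pulse train on a fixed TR tick grid: an
#' initialization epoch of continuous 3D pulses, then, for every beat, 3D
#' pulses up to the trigger delay, a 2D imaging window of
#' `projections_per_beat` TRs starting at the first tick at or after
#' R-wave + trigger delay, and 3D pulses until the next window. The radial
#' angle counter advances by `angle_increment` (mod 180) at every TR, 2D or
#' 3D; only the 2D angles are used downstream.
#'
#' @param params A [seq_params()].
#' @param timing A [cardiac_timing()].
#' @param total_beats Number of imaged heartbeats.
#' @return An object of class `epoch_schedule`: a list with `epochs`
#'   (tibble of `mode`, `start` ms, `n_tr`), the per-readout 2D `angles`
#'   (degrees), per-readout `beat` index, `tr`, and the inputs.
#' @export
build_schedule <- function(params, timing, total_beats) {
  stopifnot(inherits(params, "seq_params"), inherits(timing, "cardiac_timing"),
            total_beats >= 1)
  tr <- params$tr
  p <- params$projections_per_beat
  rr <- rr_of(timing, total_beats)
  rwave <- params$init_duration + c(0, cumsum(rr))[seq_len(total_beats)]
  win_start_tick <- ceiling((rwave + params$trigger_delay) / tr - 1e-9)
  if (p > 0 && any(diff(win_start_tick) < p)) {
    stop(sprintf(paste0("infeasible schedule: R-R interval too short for a ",
                        "%d-projection (%.1f ms) 2D window"), p, p * tr))
  }
  init_tr <- win_start_tick[1]
  epochs <- list(tibble::tibble(mode = "3D", start = 0, n_tr = init_tr))
  if (p > 0) {
    for (i in seq_len(total_beats)) {
      epochs[[length(epochs) + 1L]] <-
        tibble::tibble(mode = "2D", start = win_start_tick[i] * tr, n_tr = p)
      nxt <- if (i < total_beats) win_start_tick[i + 1] else win_start_tick[i] + p
      gap <- nxt - (win_start_tick[i] + p)
      if (gap > 0) {
        epochs[[length(epochs) + 1L]] <-
          tibble::tibble(mode = "3D", start = (win_start_tick[i] + p) * tr,
                         n_tr = gap)
      }
    }
  }
  epochs <- do.call(rbind, epochs)
  ro_ticks <- if (p > 0) {
    as.vector(outer(seq_len(p) - 1L, win_start_tick, `+`))
  } else integer(0)
  angles <- (ro_ticks * params$angle_increment) %% 180
  structure(list(epochs = epochs,
                 angles = angles,
                 beat = if (p > 0) rep(seq_len(total_beats), each = p) else integer(0),
                 readout_time = ro_ticks * tr,
                 tr = tr, params = params, timing = timing,
                 total_beats = total_beats),
            class = "epoch_schedule")
}

#' @export
print.epoch_schedule <- function(x, ...) {
  cat(sprintf("<epoch_schedule> %d beats, %d 2D readouts, %d epochs, TR %.2f ms\n",
              x$total_beats, length(x$angles), nrow(x$epochs), x$tr))
  invisible(x)
}

#' Out-of-slice magnetization under the hybrid schedule
#'
#' Evolves a spin pool that is excited during every 3D epoch (the slab
#' covers it) but relaxes freely during 2D windows (the slice-selective
#' pulses miss it). Reports the per-TR longitudinal magnetization and, per
#' beat, the relative deviation from the SPGR steady state at the first tick
#' of each 2D window — the quantity that must stay small for the imaged
#' slice to be free of in-flow and through-plane-motion contrast.
#'
#' @param schedule An [build_schedule()] result.
#' @param pool A [spin_pool()]; starts at equilibrium by default.
#' @param fa Drive flip angle (degrees).
#' @return A tibble with `time` (ms), `mz`, and `mode`, with attribute
#'   `deviation`: a tibble of per-beat relative deviations at the start of
#'   each 2D window.
#' @export
simulate_out_of_slice_mz <- function(schedule, pool, fa) {
  stopifnot(inherits(schedule, "epoch_schedule"), inherits(pool, "spin_pool"))
  tr <- schedule$tr
  ss <- spgr_steady_state(pool$t1, tr, fa)$mz_ss * pool$m0
  lam_drive <- exp(-tr / pool$t1) * cos(deg2rad(fa))
  lam_free <- exp(-tr / pool$t1)
  mz0 <- pool$mz
  out_t <- vector("list", nrow(schedule$epochs))
  out_m <- vector("list", nrow(schedule$epochs))
  dev_beat <- numeric(0)
  beat <- 0L
  for (e in seq_len(nrow(schedule$epochs))) {
    n <- schedule$epochs$n_tr[e]
    k <- seq_len(n) - 1L
    if (schedule$epochs$mode[e] == "3D") {
      mzk <- ss + (mz0 - ss) * lam_drive^k       # value entering tick k
      mz0 <- ss + (mz0 - ss) * lam_drive^n
    } else {
      beat <- beat + 1L
      dev_beat[beat] <- abs(mz0 - ss) / ss
      mzk <- pool$m0 + (mz0 - pool$m0) * lam_free^k
      mz0 <- pool$m0 + (mz0 - pool$m0) * lam_free^n
    }
    out_t[[e]] <- schedule$epochs$start[e] + k * tr
    out_m[[e]] <- mzk
  }
  res <- tibble::tibble(
    time = unlist(out_t), mz = unlist(out_m),
    mode = rep(schedule$epochs$mode, schedule$epochs$n_tr))
  attr(res, "deviation") <- tibble::tibble(beat = seq_along(dev_beat),
                                           deviation = dev_beat)
  attr(res, "mz_ss") <- ss
  res
}

# per-beat deviation recursion without materializing the full trace
oos_worst_deviation <- function(heart_rate, fa, t1, params, n_beats = 60,
                                last = 20) {
  tr <- params$tr
  p <- params$projections_per_beat
  rr <- 60000 / heart_rate
  rwave <- params$init_duration + (seq_len(n_beats + 1L) - 1L) * rr
  w <- ceiling((rwave + params$trigger_delay) / tr - 1e-9)
  if (p > 0 && any(diff(w) < p)) return(Inf)   # windows overlap
  ss <- spgr_steady_state(t1, tr, fa)$mz_ss
  lam_d <- exp(-tr / t1) * cos(deg2rad(fa))
  ef <- exp(-p * tr / t1)
  pull <- (1 - ss) * (1 - ef)                  # free-window pull toward m0
  delta <- (1 - ss) * lam_d^w[1]               # after initialization drive
  dev <- numeric(n_beats)
  for (i in seq_len(n_beats)) {
    dev[i] <- abs(delta) / ss                  # at start of 2D window
    delta <- pull + delta * ef                 # free 2D window (p ticks)
    drive <- w[i + 1L] - w[i] - p              # 3D ticks to next window
    delta <- delta * lam_d^drive
  }
  max(dev[seq.int(n_beats - last + 1L, n_beats)])
}

#' Highest heart rate with steady out-of-slice spins
#'
#' Sweeps heart rate in 1 bpm steps and returns the largest rate at which,
#' in the periodic (limit-cycle) regime, the out-of-slice magnetization has
#' returned to within `tol` (relative to the SPGR steady state) by the start
#' of every 2D imaging window. The deviation is evaluated over the last 20
#' of 60 simulated beats so the worst beat of the tick-quantization cycle is
#' counted, and the search is anchored at the longest pre-contrast T1 in the
#' slab (blood, 1800 ms by default) — the slowest-recovering spins.
#'
#' @param fa Drive flip angle (degrees).
#' @param t1 T1 of the out-of-slice spins (ms).
#' @param params A [seq_params()].
#' @param tol Relative deviation tolerance (fraction).
#' @param hr_max Upper end of the sweep (bpm).
#' @return Highest feasible heart rate (bpm), or 0 with a warning when no
#'   rate satisfies the tolerance.
#' @export
max_feasible_heart_rate <- function(fa, t1 = 1800, params = seq_params(),
                                    tol = 0.05, hr_max = NULL) {
  stopifnot(tol > 0)
  p <- params$projections_per_beat
  if (is.null(hr_max)) {
    hr_max <- if (p > 0) floor(60000 / (p * params$tr)) else 300
  }
  for (hr in seq.int(hr_max, 1L)) {
    if (oos_worst_deviation(hr, fa, t1, params) <= tol) return(hr)
  }
  warning("no feasible heart rate at this tolerance")
  0L
}

#' Feasible heart rate across flip angles
#'
#' @param fas Flip angles to evaluate (degrees).
#' @inheritParams max_feasible_heart_rate
#' @return A tibble with `fa` and `max_hr_bpm`.
#' @export
feasible_hr_table <- function(fas = c(3, 5, 10, 15, 20, 25, 30), t1 = 1800,
                              params = seq_params(projections_per_beat = 22),
                              tol = 0.05) {
  tibble::tibble(
    fa = fas,
    max_hr_bpm = vapply(fas, max_feasible_heart_rate, numeric(1),
                        t1 = t1, params = params, tol = tol))
}

#' Cyclic T1 tracking simulation
#'
#' Simulates the in-slice magnetization of a voxel whose T1 varies
#' periodically over the cardiac cycle (the imprint of cyclic blood-volume
#' changes on a post-contrast myocardial voxel), under continuous excitation
#' at flip angle `fa`, and converts each per-TR signal to an instantaneous
#' T1 estimate through the PD-normalized look-up table. Normalization uses
#' the PD-weighted steady-state signal at the reference T1, mirroring the
#' acquired (static) PD image.
#'
#' @param true_t1_fn Function of time (ms) returning the true T1 (ms).
#'   Defaults to a sinusoid with period equal to the R-R interval, mean
#'   `t1_ref` and `amplitude` relative excursion.
#' @param params A [seq_params()].
#' @param heart_rate Heart rate (bpm).
#' @param fa T1-weighted flip angle used for tracking (degrees).
#' @param t1_ref Reference (mean) T1 (ms) used for the PD normalization and
#'   the default sinusoid.
#' @param amplitude Relative excursion of the default sinusoid.
#' @param n_beats Number of simulated beats (the estimator settles within a
#'   few driven relaxation times; use [tracking_peak_to_trough()] on the
#'   final beats).
#' @param lut Optional [build_lut()] result matching `fa`; built on the fly
#'   otherwise.
#' @return A `t1track_tracking` tibble with `time`, `beat`, `true_t1`,
#'   `signal` and `est_t1`.
#' @export
track_t1_timeseries <- function(true_t1_fn = NULL, params = seq_params(),
                                heart_rate = 100, fa = params$fa_t1,
                                t1_ref = 1000, amplitude = 0.10,
                                n_beats = 20, lut = NULL) {
  rr <- 60000 / heart_rate
  if (is.null(true_t1_fn)) {
    true_t1_fn <- function(t) t1_ref * (1 + amplitude * sin(2 * pi * t / rr))
  }
  if (is.null(lut)) {
    prot <- params
    prot$fa_t1 <- fa
    lut <- build_lut(prot)
  }
  tr <- params$tr
  n_tr <- ceiling(n_beats * rr / tr)
  tt <- (seq_len(n_tr) - 1L) * tr
  t1_t <- true_t1_fn(tt)
  e1 <- exp(-tr / t1_t)
  ca <- cos(deg2rad(fa)); sa <- sin(deg2rad(fa))
  mz <- spgr_steady_state(t1_t[1], tr, fa)$mz_ss
  sig <- numeric(n_tr)
  for (k in seq_len(n_tr)) {
    sig[k] <- mz * sa
    mz <- (1 - e1[k]) + e1[k] * ca * mz
  }
  s_pd <- spgr_steady_state(t1_ref, tr, params$fa_pd)$signal_ss
  est <- lut_invert(lut, sig / s_pd)
  res <- tibble::tibble(time = tt, beat = floor(tt / rr) + 1L,
                        true_t1 = t1_t, signal = sig, est_t1 = est)
  class(res) <- c("t1track_tracking", class(res))
  attr(res, "fa") <- fa
  attr(res, "heart_rate") <- heart_rate
  res
}

#' Peak-to-trough amplitude of a tracking run
#'
#' @param track A [track_t1_timeseries()] result.
#' @param last_beats Number of final (settled) beats to evaluate.
#' @return A list with `true`, `estimated` (ms peak-to-trough) and `ratio`.
#' @export
tracking_peak_to_trough <- function(track, last_beats = 3) {
  keep <- track$beat > max(track$beat) - last_beats
  p2p_true <- diff(range(track$true_t1[keep]))
  p2p_est <- diff(range(track$est_t1[keep]))
  list(true = p2p_true, estimated = p2p_est, ratio = p2p_est / p2p_true)
}
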