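#' Bloch-simulation look-up table for instantaneous T1 mapping
#'
#' Tabulates the PD-normalized steady-state SPGR signal ratio
#' `r(T1) = S(fa_t1 * b1) / S(fa_pd * b1)` over a T1 grid. Under the hybrid
#' 2D/3D sequence the imaged slice is excited continuously, so each acquired
#' sample sits at the instantaneous steady state and the ratio is a strictly
#' monotone function of T1 that can be inverted pixelwise.
#'
#' @param protocol A [seq_params()] (uses `tr`, `fa_pd`, `fa_t1`).
#' @param b1_scale Relative transmit (B1+) scale the table is built for.
#' @param grid Ascending T1 grid (ms); default 100-3000 ms in 2 ms steps.
#' @return An object of class `t1_lut` with fields `t1_grid`, `ratio`,
#'   `protocol`, `b1_scale`.
#' @export
build_lut <- function(protocol = seq_params(), b1_scale = 1,
                      grid = seq(100, 3000, by = 2)) {
  stopifnot(inherits(protocol, "seq_params"))
  if (b1_scale <= 0) stop("b1_scale must be positive")
  if (protocol$fa_pd >= protocol$fa_t1) {
    stop("the PD-weighted flip angle must be below the T1-weighted one")
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("T1 grid must be ascending")
  s_hi <- spgr_steady_state(grid, protocol$tr, protocol$fa_t1 * b1_scale)$signal_ss
  s_lo <- spgr_steady_state(grid, protocol$tr, protocol$fa_pd * b1_scale)$signal_ss
  ratio <- s_hi / s_lo
  d <- diff(ratio)
  if (!(all(d > 0) || all(d < 0))) {
    bad <- which(sign(d) != sign(d[1]))[1]
    stop(sprintf("LUT ratio is not monotone over T1 in [%g, %g] ms",
                 grid[bad], grid[bad + 1]))
  }
  structure(list(t1_grid = grid, ratio = ratio, protocol = protocol,
                 b1_scale = b1_scale, decreasing = d[1] < 0),
            class = "t1_lut")
}

#' @export
print.t1_lut <- function(x, ...) {
  cat(sprintf("<t1_lut> %d nodes, T1 %g..%g ms, FA %g/%g deg, B1 %.2f\n",
              length(x$t1_grid), min(x$t1_grid), max(x$t1_grid),
              x$protocol$fa_t1, x$protocol$fa_pd, x$b1_scale))
  invisible(x)
}

#' Invert a look-up table
#'
#' Piecewise-linear inversion of the normalized-signal ratio to T1.
#' Out-of-range ratios are clamped to the grid ends and flagged.
#'
#' @param lut A [build_lut()] result.
#' @param ratio Numeric vector of PD-normalized signal ratios.
#' @return T1 values (ms) with logical attribute `out_of_range`.
#' @export
lut_invert <- function(lut, ratio) {
  stopifnot(inherits(lut, "t1_lut"))
  r <- lut$ratio; t1 <- lut$t1_grid
  if (lut$decreasing) { r <- rev(r); t1 <- rev(t1) }
  oor <- ratio < min(r) | ratio > max(r) | !is.finite(ratio)
  est <- stats::approx(r, t1, xout = pmin(pmax(ratio, min(r)), max(r)),
                       rule = 2, ties = "ordered")$y
  attr(est, "out_of_range") <- oor
  est
}

#' Family of look-up tables across transmit scales
#'
#' Precomputes one LUT per B1+ scale for per-pixel flip-angle correction.
#'
#' @param protocol A [seq_params()].
#' @param b1_grid Ascending B1 scales; default 0.6-1.4 in 0.02 steps.
#' @param grid T1 grid passed to [build_lut()].
#' @return An object of class `t1_lut_family`.
#' @export
build_lut_family <- function(protocol = seq_params(),
                             b1_grid = seq(0.6, 1.4, by = 0.02),
                             grid = seq(100, 3000, by = 2)) {
  luts <- lapply(b1_grid, function(b) build_lut(protocol, b, grid))
  structure(list(b1_grid = b1_grid, luts = luts, protocol = protocol),
            class = "t1_lut_family")
}

#' PD normalization of a T1-weighted image
#'
#' Divides the T1-weighted image by the PD-weighted image pixelwise inside
#' the mask, removing coil sensitivity, proton density and the constant
#' T2*(TE) attenuation. Pixels whose PD magnitude falls below
#' `floor` times a robust maximum (99th percentile inside the mask) are
#' removed from the mask instead of producing unstable ratios.
#'
#' @param t1w,pd Congruent [map_image()]s.
#' @param floor Fraction of the robust PD maximum below which pixels are
#'   masked out.
#' @return A ratio [map_image()] (units `"a.u."`).
#' @export
normalize_pd <- function(t1w, pd, floor = 0.05) {
  stopifnot(inherits(t1w, "map_image"), inherits(pd, "map_image"))
  if (!all(dim(t1w$values) == dim(pd$values))) {
    stop("T1-weighted and PD-weighted images have different grids")
  }
  pdv <- Mod(pd$values)
  mask <- t1w$mask & pd$mask
  robust_max <- stats::quantile(pdv[mask], 0.99, names = FALSE)
  mask <- mask & (pdv > floor * robust_max)
  vals <- matrix(0, nrow(pdv), ncol(pdv))
  vals[mask] <- Mod(t1w$values[mask]) / pdv[mask]
  map_image(vals, pixel_spacing = t1w$pixel_spacing, units = "a.u.",
            mask = mask, phase = t1w$phase, contrast = t1w$contrast)
}

#' Fit a T1 map from a PD-normalized ratio image
#'
#' Inverts the look-up table pixelwise. With a B1+ map, the inversion is
#' interpolated linearly across a precomputed family of per-B1 tables
#' (bilinear in ratio and B1). Ratios outside the table are clamped to the
#' grid ends and dropped from the mask.
#'
#' @param ratio A ratio [map_image()] from [normalize_pd()].
#' @param lut A [build_lut()] result (used when `b1_map` is `NULL`).
#' @param b1_map Optional relative transmit-scale [map_image()].
#' @param lut_family Optional [build_lut_family()]; required with `b1_map`.
#' @return A T1 [map_image()] (ms).
#' @export
fit_t1_map <- function(ratio, lut = NULL, b1_map = NULL, lut_family = NULL) {
  stopifnot(inherits(ratio, "map_image"))
  vals <- matrix(NA_real_, nrow(ratio$values), ncol(ratio$values))
  mask <- ratio$mask
  rv <- ratio$values[mask]
  if (is.null(b1_map)) {
    if (is.null(lut)) stop("either lut or (b1_map, lut_family) must be given")
    est <- lut_invert(lut, rv)
    oor <- attr(est, "out_of_range")
  } else {
    if (is.null(lut_family)) stop("a lut_family is required with a b1_map")
    b1 <- pmin(pmax(b1_map$values[mask], min(lut_family$b1_grid)),
               max(lut_family$b1_grid))
    idx <- findInterval(b1, lut_family$b1_grid, rightmost.closed = TRUE)
    lo <- lut_family$b1_grid[idx]
    hi <- lut_family$b1_grid[pmin(idx + 1L, length(lut_family$b1_grid))]
    w <- ifelse(hi > lo, (b1 - lo) / (hi - lo), 0)
    est <- numeric(length(rv)); oor <- logical(length(rv))
    for (i in unique(idx)) {
      sel <- idx == i
      e_lo <- lut_invert(lut_family$luts[[i]], rv[sel])
      e_hi <- lut_invert(lut_family$luts[[min(i + 1L, length(lut_family$luts))]],
                         rv[sel])
      est[sel] <- (1 - w[sel]) * e_lo + w[sel] * e_hi
      oor[sel] <- attr(e_lo, "out_of_range") & attr(e_hi, "out_of_range")
    }
  }
  keep <- mask
  keep[mask] <- !oor
  vals[mask] <- est
  vals[!keep] <- 0
  map_image(vals, pixel_spacing = ratio$pixel_spacing, units = "ms",
            mask = keep, phase = ratio$phase, contrast = ratio$contrast)
}
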