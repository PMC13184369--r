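#' Reconstruction configuration
#'
#' @param mode `"gridded"` (density-compensated adjoint gridding with
#'   root-sum-of-squares coil combination) or `"cg_sense"` (iterative
#'   conjugate-gradient SENSE).
#' @param cg_iterations Maximum CG iterations.
#' @param cg_tolerance Relative residual at which CG stops.
#' @param density_comp `"ramp"` or `"voronoi"` (radial-annulus areas with
#'   per-projection angular gaps).
#' @param kernel_width Gridding kernel width (grid cells).
#' @param oversampling Grid oversampling factor (`>= 1.25`).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(mode = c("cg_sense", "gridded"), cg_iterations = 15,
                         cg_tolerance = 1e-6, density_comp = c("ramp", "voronoi"),
                         kernel_width = 4, oversampling = 2) {
  mode <- match.arg(mode)
  density_comp <- match.arg(density_comp)
  stopifnot(cg_iterations >= 1, cg_tolerance > 0, kernel_width >= 2,
            oversampling >= 1.25)
  structure(list(mode = mode, cg_iterations = cg_iterations,
                 cg_tolerance = cg_tolerance, density_comp = density_comp,
                 kernel_width = kernel_width, oversampling = oversampling),
            class = "recon_config")
}

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}
# even sizes only, so shift and inverse shift coincide
ifftshift2 <- fftshift2

kb_kernel <- function(d, width, beta) {
  t <- 1 - (2 * d / width)^2
  w <- numeric(length(d))
  ok <- t > 0
  w[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  w
}

#' Plan a non-uniform Fourier transform
#'
#' Precomputes the sparse Kaiser-Bessel interpolation operator and the
#' matching (numerically computed) apodization for evaluating
#' `s(k) = sum_x m(x) exp(-2i pi k.x)` at arbitrary sample locations via an
#' oversampled FFT. The forward and adjoint operators are exact transposes
#' of each other by construction.
#'
#' @param kx,ky Sample coordinates (cycles/pixel, in `[-0.5, 0.5)`).
#' @param n Image matrix size (even).
#' @param oversampling Grid oversampling factor.
#' @param width Kernel width in oversampled grid cells.
#' @return An object of class `nufft_plan`.
#' @export
nufft_plan <- function(kx, ky, n, oversampling = 2, width = 4) {
  stopifnot(length(kx) == length(ky), n %% 2 == 0)
  m <- 2L * ceiling(n * oversampling / 2)
  os <- m / n
  beta <- pi * sqrt((width / os * (os - 0.5))^2 - 0.8)
  ns <- length(kx)
  half <- width / 2
  build_dim <- function(u) {
    l0 <- floor(u) - half + 1L
    l <- outer(l0, 0:(width - 1L), `+`)            # ns x width integer grid
    w <- kb_kernel(u - l, width, beta)
    dim(w) <- dim(l)
    idx <- ((l + m / 2) %% m) + 1L                 # wrapped fftshifted index
    list(idx = idx, w = w)
  }
  d1 <- build_dim(kx * m)
  d2 <- build_dim(ky * m)
  rows <- rep(seq_len(ns), width * width)
  a <- rep(seq_len(width), times = width)
  b <- rep(seq_len(width), each = width)
  cols <- as.vector(d1$idx[, a]) + (as.vector(d2$idx[, b]) - 1L) * m
  vals <- as.vector(d1$w[, a]) * as.vector(d2$w[, b])
  g <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(ns, m * m))
  # apodization = centered DFT of the sampled kernel, cropped to the image
  kg <- numeric(m)
  j <- seq(-m / 2, m / 2 - 1)
  kg[abs(j) <= half] <- kb_kernel(j[abs(j) <= half], width, beta)
  c1 <- Re(fftshift2_1(stats::fft(fftshift2_1(kg))))
  keep <- (m / 2 - n / 2 + 1):(m / 2 + n / 2)
  apod <- outer(c1[keep], c1[keep])
  structure(list(g = g, n = n, m = m, apod = apod, ns = ns,
                 kx = kx, ky = ky, width = width, beta = beta),
            class = "nufft_plan")
}

fftshift2_1 <- function(x) {
  n <- length(x)
  x[c((n / 2 + 1):n, 1:(n / 2))]
}

sp_cmult <- function(g, z, transpose = FALSE) {
  if (transpose) {
    as.vector(Matrix::crossprod(g, Re(z))) + 1i * as.vector(Matrix::crossprod(g, Im(z)))
  } else {
    as.vector(g %*% Re(z)) + 1i * as.vector(g %*% Im(z))
  }
}

#' Apply a NUFFT plan
#'
#' `nufft_forward` maps an `n x n` complex image to the planned k-space
#' samples; `nufft_adjoint` is its exact adjoint.
#'
#' @param plan A [nufft_plan()].
#' @param x Complex image matrix (forward) or sample vector (adjoint).
#' @return Sample vector (forward) or image matrix (adjoint).
#' @export
nufft_forward <- function(plan, x) {
  m <- plan$m; n <- plan$n
  xp <- matrix(0 + 0i, m, m)
  keep <- (m / 2 - n / 2 + 1):(m / 2 + n / 2)
  xp[keep, keep] <- x / plan$apod
  spec <- fftshift2(stats::fft(ifftshift2(xp)))
  sp_cmult(plan$g, as.vector(spec))
}

#' @rdname nufft_forward
#' @export
nufft_adjoint <- function(plan, x) {
  m <- plan$m; n <- plan$n
  spec <- matrix(sp_cmult(plan$g, x, transpose = TRUE), m, m)
  xp <- fftshift2(stats::fft(ifftshift2(spec), inverse = TRUE))
  keep <- (m / 2 - n / 2 + 1):(m / 2 + n / 2)
  xp[keep, keep] / plan$apod
}

# batched multi-coil application: one sparse product for all coils
nufft_forward_multi <- function(plan, x_arr) {
  m <- plan$m; n <- plan$n
  nc <- dim(x_arr)[3]
  keep <- (m / 2 - n / 2 + 1):(m / 2 + n / 2)
  specs <- matrix(0 + 0i, m * m, nc)
  for (c in seq_len(nc)) {
    xp <- matrix(0 + 0i, m, m)
    xp[keep, keep] <- x_arr[, , c] / plan$apod
    specs[, c] <- as.vector(fftshift2(stats::fft(ifftshift2(xp))))
  }
  as.matrix(plan$g %*% Re(specs)) + 1i * as.matrix(plan$g %*% Im(specs))
}

nufft_adjoint_multi <- function(plan, s_mat) {
  m <- plan$m; n <- plan$n
  nc <- ncol(s_mat)
  keep <- (m / 2 - n / 2 + 1):(m / 2 + n / 2)
  specs <- as.matrix(Matrix::crossprod(plan$g, Re(s_mat))) +
    1i * as.matrix(Matrix::crossprod(plan$g, Im(s_mat)))
  out <- array(0 + 0i, c(n, n, nc))
  for (c in seq_len(nc)) {
    xp <- fftshift2(stats::fft(ifftshift2(matrix(specs[, c], m, m)),
                               inverse = TRUE))
    out[, , c] <- xp[keep, keep] / plan$apod
  }
  out
}

#' Exact non-uniform DFT (oracle-grade)
#'
#' Direct evaluation of `s(k) = sum_x m(x) exp(-2i pi k.x)`, chunked per
#' projection. Quadratic cost; intended for small matrices and as the
#' accuracy oracle for the gridding operator.
#'
#' @param kx,ky Sample coordinates (cycles/pixel).
#' @param img Complex image matrix (centered pixel coordinates).
#' @return Complex sample vector.
#' @export
nudft_forward <- function(kx, ky, img) {
  n1 <- nrow(img); n2 <- ncol(img)
  x <- seq(-n1 / 2, n1 / 2 - 1)
  y <- seq(-n2 / 2, n2 / 2 - 1)
  v <- as.vector(img)
  xx <- rep(x, times = n2); yy <- rep(y, each = n1)
  out <- complex(length(kx))
  chunk <- max(1L, floor(2e6 / length(v)))
  for (s in seq(1, length(kx), by = chunk)) {
    e <- min(s + chunk - 1L, length(kx))
    ph <- exp(-2i * pi * (outer(kx[s:e], xx) + outer(ky[s:e], yy)))
    out[s:e] <- as.vector(ph %*% v)
  }
  out
}

#' Pool the projections of one cardiac phase
#'
#' Subsets a radial acquisition to the projections labeled with the
#' requested phase, preserving order.
#'
#' @param k A [radial_kspace] object.
#' @param phase `"ES"` or `"ED"`.
#' @return A `radial_kspace` with only the requested projections.
#' @export
pool_projections <- function(k, phase) {
  stopifnot(inherits(k, "radial_kspace"))
  sel <- k$phase_label == phase
  if (!any(sel)) stop(sprintf("no projections labeled %s in this acquisition", phase))
  k$samples <- k$samples[, sel, , drop = FALSE]
  k$angles <- k$angles[sel]
  k$beat <- k$beat[sel]
  k$phase_label <- k$phase_label[sel]
  k
}

density_weights <- function(k, config) {
  nro <- dim(k$samples)[1]
  r <- abs(((seq_len(nro) - 1) - nro / 2) / nro)
  r[r == 0] <- 1 / (4 * nro)
  nproj <- dim(k$samples)[2]
  if (config$density_comp == "ramp") {
    w_ang <- rep(pi / nproj, nproj)
  } else {
    a <- (k$angles %% 180) * pi / 180
    o <- order(a)
    gaps <- diff(c(a[o], a[o[1]] + pi))
    half <- (gaps + c(gaps[length(gaps)], gaps[-length(gaps)])) / 2
    w_ang <- numeric(nproj)
    w_ang[o] <- half
  }
  outer(r, w_ang)
}

kspace_plan <- function(k, config) {
  nufft_plan(as.vector(k$kx), as.vector(k$ky), k$n,
             oversampling = config$oversampling, width = config$kernel_width)
}

#' Density-compensated gridding reconstruction
#'
#' Adjoint NUFFT of density-compensated samples, coil-combined by
#' root-sum-of-squares. Output intensity is on an arbitrary (consistent)
#' scale, as usual for gridding.
#'
#' @param k A [radial_kspace] object.
#' @param config A [recon_config()].
#' @param plan Optional precomputed [nufft_plan()] for this trajectory.
#' @return A magnitude [map_image()].
#' @export
gridded_recon <- function(k, config = recon_config(mode = "gridded"),
                          plan = NULL) {
  stopifnot(inherits(k, "radial_kspace"))
  if (is.null(plan)) plan <- kspace_plan(k, config)
  w <- as.vector(density_weights(k, config))
  nc <- dim(k$samples)[3]
  acc <- matrix(0, k$n, k$n)
  for (c in seq_len(nc)) {
    img <- nufft_adjoint(plan, as.vector(k$samples[, , c]) * w)
    acc <- acc + Mod(img)^2
  }
  px <- k$fov / k$n
  map_image(sqrt(acc) / sum(w), pixel_spacing = px, units = "a.u.",
            phase = k$phase_label[1], contrast = k$contrast)
}

#' Conjugate-gradient SENSE reconstruction
#'
#' Solves the coil-sensitivity-encoded non-Cartesian Fourier inverse problem
#' in the density-weighted least-squares sense, by conjugate gradients on
#' the normal equations. Returns the magnitude image with the CG residual
#' history attached; the solver aborts if the residual fails to decrease
#' over five consecutive iterations.
#'
#' @param k A [radial_kspace] object.
#' @param sens Complex array `n x n x n_coils` of coil sensitivities.
#' @param config A [recon_config()].
#' @param plan Optional precomputed [nufft_plan()].
#' @return A magnitude [map_image()] with attributes `residuals` (relative
#'   residual per iteration) and `complex_image`.
#' @export
cg_sense_recon <- function(k, sens, config = recon_config(), plan = NULL) {
  stopifnot(inherits(k, "radial_kspace"))
  nc <- dim(k$samples)[3]
  stopifnot(dim(sens)[3] == nc, dim(sens)[1] == k$n)
  if (is.null(plan)) plan <- kspace_plan(k, config)
  w <- as.vector(density_weights(k, config))
  forward <- function(x) {
    xs <- array(0 + 0i, c(k$n, k$n, nc))
    for (c in seq_len(nc)) xs[, , c] <- sens[, , c] * x
    nufft_forward_multi(plan, xs)
  }
  adjoint <- function(s) {
    imgs <- nufft_adjoint_multi(plan, s * w)
    acc <- matrix(0 + 0i, k$n, k$n)
    for (c in seq_len(nc)) acc <- acc + Conj(sens[, , c]) * imgs[, , c]
    acc
  }
  y <- matrix(as.vector(k$samples), ncol = nc)
  b <- adjoint(y)
  normal_op <- function(x) adjoint(forward(x))
  x <- matrix(0 + 0i, k$n, k$n)
  r <- b
  p <- r
  rs <- sum(Mod(r)^2)
  b0 <- sqrt(sum(Mod(b)^2))
  hist <- numeric(0)
  bad <- 0
  for (it in seq_len(config$cg_iterations)) {
    ap <- normal_op(p)
    alpha <- rs / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    hist[it] <- sqrt(rs_new) / b0
    if (it > 1 && hist[it] >= hist[it - 1]) bad <- bad + 1 else bad <- 0
    if (bad >= 5) stop(sprintf(
      "CG residual non-decreasing over 5 iterations (last %.3g)", hist[it]))
    if (hist[it] < config$cg_tolerance) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  px <- k$fov / k$n
  out <- map_image(Mod(x), pixel_spacing = px, units = "a.u.",
                   phase = k$phase_label[1], contrast = k$contrast)
  attr(out, "residuals") <- hist
  attr(out, "complex_image") <- x
  out
}

#' Normalized root-mean-square error between images
#'
#' `||a x - ref|| / ||ref||`, with `a` either 1 (`scale = "none"`) or the
#' least-squares optimal scalar (`scale = "optimal"`, appropriate when the
#' reconstruction has an arbitrary global intensity scale).
#'
#' @param x,ref Numeric matrices or [map_image()]s.
#' @param scale `"optimal"` or `"none"`.
#' @return The NRMSE (fraction).
#' @export
nrmse <- function(x, ref, scale = c("optimal", "none")) {
  scale <- match.arg(scale)
  if (inherits(x, "map_image")) x <- x$values
  if (inherits(ref, "map_image")) ref <- ref$values
  a <- if (scale == "optimal") sum(x * ref) / sum(x^2) else 1
  sqrt(sum((a * x - ref)^2) / sum(ref^2))
}
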