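# Independent oracles used across the suite.

# forward-Euler integration of dMz/dt = (m0 - mz)/t1
euler_relax <- function(mz, m0, t1, dt, steps = 1000) {
  h <- dt / steps
  for (i in seq_len(steps)) mz <- mz + h * (m0 - mz) / t1
  mz
}

# SPGR steady state by iterating excite + relax to convergence
iterate_spgr <- function(t1, tr, fa, tol = 1e-14, max_iter = 1e6) {
  p <- spin_pool(t1)
  fa_rad <- fa * pi / 180
  e1 <- exp(-tr / t1)
  mz <- 1
  repeat {
    mz_new <- 1 - e1 + e1 * cos(fa_rad) * mz
    if (abs(mz_new - mz) < tol || (max_iter <- max_iter - 1) == 0) break
    mz <- mz_new
  }
  list(mz_ss = mz, signal_ss = mz * sin(fa_rad))
}

# fine-step time-domain integration of the two-pool longitudinal
# Bloch-McConnell equations over one TR
euler_two_pool <- function(m, tissue, tr, contrast, steps = 4000) {
  r1b <- 1000 / switch(contrast, pre = tissue$t1_blood_pre,
                       post = tissue$t1_blood_post)
  r1e <- 1000 / tissue$t1_ev
  k_be <- 1000 / tissue$tau_b
  k_eb <- k_be * tissue$f_v / (1 - tissue$f_v)
  meq <- tissue$m0 * c(tissue$f_v, 1 - tissue$f_v)
  h <- tr / 1000 / steps
  for (i in seq_len(steps)) {
    d1 <- r1b * (meq[1] - m[1]) - k_be * m[1] + k_eb * m[2]
    d2 <- r1e * (meq[2] - m[2]) + k_be * m[1] - k_eb * m[2]
    m <- m + h * c(d1, d2)
  }
  m
}

# small uniform-disk image, rasterized with subpixel area sampling and
# aligned with the DFT's integer pixel-centre convention
disk_image <- function(n, radius_px, sub = 32) {
  nn <- n * sub
  x <- (seq_len(nn) - (sub + 1) / 2) / sub - n / 2
  inside <- outer(x^2, x^2, `+`) <= radius_px^2
  t1track:::box_downsample(inside * 1, sub)
}

default_study_tissue <- function(f_v, tau_b = 150) {
  two_compartment_tissue(f_v, t1_blood_pre = 1820, t1_blood_post = 289,
                         t1_ev = 1185.6, tau_b = tau_b)
}
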