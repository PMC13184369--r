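test_that("the fast-exchange and no-exchange estimators follow their formulas", {
  # no tissue change -> zero fraction
  expect_equal(imbv_fast_exchange(contrast_pair(1493, 1493, 1820, 289)), 0)
  # study-group mean T1s
  expect_equal(imbv_fast_exchange(contrast_pair(1493, 985, 1820, 289)),
               0.1187, tolerance = 1e-3)
  # a 200 ms pre-contrast blood underestimate moves the estimate by ~3%
  true_fv <- imbv_fast_exchange(contrast_pair(1493, 985, 1800, 340))
  off_fv <- imbv_fast_exchange(contrast_pair(1493, 985, 1600, 340))
  expect_equal(abs(off_fv / true_fv - 1), 0.030, tolerance = 1e-3)
  expect_error(imbv_fast_exchange(contrast_pair(1493, 985, 500, 500)),
               "undefined")

  expect_equal(imbv_no_exchange(contrast_pair(0.04, 0.04, 0.03, 0.19)), 0)
  expect_equal(imbv_no_exchange(contrast_pair(0.03, 0.19, 0.03, 0.19)), 1)
  expect_equal(imbv_no_exchange(contrast_pair(0.040, 0.062, 0.030, 0.190)),
               0.1375, tolerance = 1e-10)
  expect_error(imbv_no_exchange(contrast_pair(0.04, 0.06, 0.1, 0.1)))
})

test_that("the exchange-independence condition shrinks with flip angle", {
  expect_equal(exchange_independence_lhs(4.5, 289, 90), 0)
  expect_equal(exchange_independence_lhs(4.5, 289, 20), 0.2426,
               tolerance = 1e-3)
  expect_equal(exchange_independence_lhs(4.5, 289, 70), 0.0081,
               tolerance = 2e-2)
  expect_error(exchange_independence_lhs(4.5, 289, 0))
  fas <- seq(5, 90, by = 5)
  expect_true(all(diff(exchange_independence_lhs(4.5, 289, fas)) < 0))
})

test_that("the two-pool SPGR signal hits both closed-form limits", {
  fv <- 0.077
  # fast-exchange limit: single pool at the volume-averaged R1
  fast <- default_study_tissue(fv, tau_b = 1e-6)
  r1 <- fv * 1000 / 289 + (1 - fv) * 1000 / 1185.6
  expect_equal(two_pool_spgr_signal(fast, 4.5, 20, "post")$signal,
               spgr_steady_state(1000 / r1, 4.5, 20)$signal_ss,
               tolerance = 1e-6)
  # no-exchange limit: volume-weighted sum of independent pools
  frozen <- default_study_tissue(fv, tau_b = Inf)
  indep <- fv * spgr_steady_state(289, 4.5, 20)$signal_ss +
    (1 - fv) * spgr_steady_state(1185.6, 4.5, 20)$signal_ss
  expect_equal(two_pool_spgr_signal(frozen, 4.5, 20, "post")$signal, indep,
               tolerance = 1e-12)
  # intermediate residence time: strictly between the limits
  mid <- two_pool_spgr_signal(default_study_tissue(fv, 150), 4.5, 20,
                              "post")$signal
  lo <- min(indep, two_pool_spgr_signal(fast, 4.5, 20, "post")$signal)
  hi <- max(indep, two_pool_spgr_signal(fast, 4.5, 20, "post")$signal)
  expect_gt(mid, lo)
  expect_lt(mid, hi)

  # fine-step time-domain integration oracle for one TR of free evolution
  tis <- default_study_tissue(fv, 150)
  a <- t1track:::exchange_generator(tis, "post")
  m0 <- c(0.02, 0.5)
  meq <- c(fv, 1 - fv)
  prop <- t1track:::expm2_neg(a, 4.5 / 1000)
  expect_equal(as.numeric(meq + prop %*% (m0 - meq)),
               euler_two_pool(m0, tis, 4.5, "post"), tolerance = 1e-6)

  # magnetization conservation: at zero flip the fixed point is equilibrium
  expect_equal(two_pool_spgr_signal(tis, 4.5, 0, "post")$mz, meq,
               tolerance = 1e-12)
})

test_that("exchange regime barely biases the relative ES-to-ED change", {
  lut <- build_lut()
  # infinite exchange rate: the pipeline reproduces the fast reference
  b0 <- relative_es_ed_bias(default_study_tissue(0.062, 1e-6),
                            default_study_tissue(0.077, 1e-6), lut = lut)
  expect_lt(b0$bias_rel, 1e-6)

  # porcine-plausible residence times: < 5% relative, < 1 point absolute
  for (tb in c(100, 150, 200)) {
    b <- relative_es_ed_bias(default_study_tissue(0.062, tb),
                             default_study_tissue(0.077, tb), lut = lut)
    expect_lt(b$bias_rel, 0.05)
    expect_lt(b$bias_abs, 0.01)
  }

  # approaching from the slow-exchange side, the bias decays monotonically
  # with the exchange rate (it changes sign near tau_b ~ 100 ms, so the
  # magnitude is compared down to that point on a log grid)
  tbs <- c(800, 400, 200, 100)
  biases <- vapply(tbs, function(tb) {
    relative_es_ed_bias(default_study_tissue(0.062, tb),
                        default_study_tissue(0.077, tb), lut = lut)$bias_rel
  }, numeric(1))
  expect_true(all(diff(biases) < 0))
})

test_that("fast/no-exchange estimates converge with flip angle and agree in the fast limit", {
  tbl <- fv_convergence_table(fv_true = c(0.269, 0.155),
                              fas = c(10, 20, 30, 40, 70))
  for (fv in c(0.269, 0.155)) {
    gap <- abs(tbl$fv_fast[tbl$fv_true == fv] - tbl$fv_noex[tbl$fv_true == fv])
    # the estimators converge monotonically up to the crossing (~40 deg)
    expect_true(all(diff(gap[tbl$fa[tbl$fv_true == fv] <= 40]) < 0))
    # at high FA both estimators approach the truth
    expect_lt(abs(tbl$fv_fast[tbl$fv_true == fv & tbl$fa == 70] - fv) / fv,
              0.05)
    expect_lt(abs(tbl$fv_noex[tbl$fv_true == fv & tbl$fa == 70] - fv) / fv,
              0.05)
  }
  # the ratio of the two fractions is stable across FA (within 5%)
  ratio <- tbl$fv_fast[tbl$fv_true == 0.269] / tbl$fv_fast[tbl$fv_true == 0.155]
  expect_true(all(abs(ratio / (0.269 / 0.155) - 1) < 0.05))

  # when signals are generated in the exact fast-exchange limit and the
  # apparent T1s are the mixed single-pool values, the two formulas agree
  fv <- 0.2
  mix <- function(contrast) {
    t1track:::mixed_t1(default_study_tissue(fv), fv, contrast)
  }
  sig <- function(t1, fa) spgr_steady_state(t1, 4.5, fa)$signal_ss
  f1 <- imbv_fast_exchange(contrast_pair(mix("pre"), mix("post"), 1820, 289))
  f2 <- imbv_no_exchange(contrast_pair(
    tissue_pre = fv * sig(1820, 20) + (1 - fv) * sig(1185.6, 20),
    tissue_post = fv * sig(289, 20) + (1 - fv) * sig(1185.6, 20),
    blood_pre = sig(1820, 20), blood_post = sig(289, 20)))
  # both recover fv in their own consistent regime
  expect_equal(f1, fv, tolerance = 1e-12)
  expect_equal(f2, fv, tolerance = 1e-12)
})
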