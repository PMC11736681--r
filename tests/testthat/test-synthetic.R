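test_that("transient fit recovers noise-free parameters and rejects negative fast terms", {
  tt <- seq(0, 30, by = 8e-4)
  dt <- 8e-4

  flat <- fit_transient(sim_series(rep(0.7, length(tt)), dt = dt), window = 10)
  expect_equal(flat$a_slow, 0)

  single <- fit_transient(sim_series(2 * 2^(-tt / 1.0), dt = dt),
                          window = 10, baseline = 0)
  expect_equal(single$a_slow, 2, tolerance = 1e-6)
  expect_equal(single$hl_slow, 1.0, tolerance = 1e-6)
  expect_equal(single$a_fast, 0)

  biexp <- fit_transient(
    sim_series(2 * 2^(-tt / 1.0) + 14 * 2^(-tt / 0.004), dt = dt),
    window = 10, baseline = 0
  )
  expect_equal(biexp$a_slow, 2, tolerance = 1e-6)
  expect_equal(biexp$hl_slow, 1.0, tolerance = 1e-6)
  expect_equal(biexp$a_fast, 14, tolerance = 1e-6)
  expect_equal(biexp$hl_fast, 0.004, tolerance = 1e-6)

  rejected <- fit_transient(
    sim_series(2 * 2^(-tt / 1.0) - 5 * 2^(-tt / 0.004), dt = dt),
    window = 10, baseline = 0
  )
  expect_equal(rejected$a_fast, 0)
})

test_that("autocovariance model fitting recovers a known generator", {
  # white-noise-like input: short memory, gamma_0 near the sample variance
  set.seed(8)
  wn <- sim_series(rnorm(4000), dt = 1)
  m_wn <- fit_autocov_model(wn)
  expect_equal(m_wn$gamma[1], var(wn$values) * (3999 / 4000), tolerance = 1e-6)
  expect_lt(m_wn$max_lag_index, 60)

  # round trip: generate from an exponential autocovariance, refit
  gamma_true <- 1.0 * 2^(-(0:20) / 3)
  acv <- autocov_model(gamma_true, dt = 1)
  ens <- generate_ensemble(transient_model(0, Inf), acv, 1, 20000, seed = 14)
  fit <- fit_autocov_model(ensemble_series(ens, 1))
  expect_equal(fit$gamma[1], gamma_true[1], tolerance = 0.1)
  expect_equal(fit$gamma[2], gamma_true[2], tolerance = 0.15)
  # reconstructed tail decays and roughly tracks the generator scale
  expect_equal(sum(fit$gamma[3:8]), sum(gamma_true[3:8]), tolerance = 0.35)

  expect_error(fit_autocov_model(sim_series(rep(1, 100))), "constant")
})

test_that("interpolated lag pairs of a fitted model sum back to the convex sequence", {
  s <- ar1_series(5000, 0.6, seed = 3)
  fit <- fit_autocov_model(s)
  g <- fit$gamma
  L <- fit$max_lag_index
  if (L >= 5) {
    # interior pairs (2m, 2m+1), m >= 1, each reconstruct one Gamma value
    pair_sums <- g[seq(3, L, by = 2)] + g[seq(4, L + 1, by = 2)]
    expect_true(all(diff(pair_sums) <= 1e-12))
    expect_true(all(pair_sums > 0))
  }
})

test_that("generated white-noise ensembles reproduce their target moments", {
  acv <- autocov_model(1, dt = 1)
  ens <- generate_ensemble(transient_model(0, Inf), acv, 1000, 200, seed = 11)
  g0 <- mean(apply(ens$values, 2, function(v) acv_brute(v, 0)))
  g1 <- mean(apply(ens$values, 2, function(v) acv_brute(v, 1)))
  expect_equal(g0, 1, tolerance = 0.02)
  expect_equal(g1, 0, tolerance = 0.02)
  # per-series means average to the true mean of zero
  expect_equal(mean(colMeans(ens$values)), 0, tolerance = 0.01)
})

test_that("ensemble-average autocovariance matches the generating model", {
  gamma_true <- 0.8 * 2^(-(0:15) / 4)
  acv <- autocov_model(gamma_true, dt = 1)
  ens <- generate_ensemble(transient_model(0, Inf), acv, 300, 500, seed = 23)
  for (lag in 0:5) {
    g_hat <- mean(apply(ens$values, 2, acv_brute, lag = lag))
    # per-series estimates carry an O(sum(gamma)/N) centering bias
    expect_equal(g_hat, gamma_true[lag + 1], tolerance = 0.08)
  }
})

test_that("transients shift the ensemble as constructed", {
  acv <- autocov_model(c(0.01), dt = 0.1)
  tr <- transient_model(2, 1, a_fast = 0.5, hl_fast = 0.01)
  ens <- generate_ensemble(tr, acv, 400, 50, seed = 31)
  expect_equal(mean(ens$values[1, ]), 2.5, tolerance = 0.05)
  expect_equal(ens$true_mean, 0)
})

test_that("ensembles are reproducible and extensible under one root seed", {
  acv <- autocov_model(0.5 * 2^(-(0:6) / 2), dt = 1)
  tr <- transient_model(1, 0.5)
  a <- generate_ensemble(tr, acv, 8, 100, seed = 99)
  b <- generate_ensemble(tr, acv, 8, 100, seed = 99)
  expect_identical(a$values, b$values)
  bigger <- generate_ensemble(tr, acv, 12, 100, seed = 99)
  expect_identical(bigger$values[, 1:8], a$values)
})

test_that("presets carry the recorded transients and calibrated total variance", {
  p <- abfe_presets()
  expect_named(p, c("T4L", "MIF", "MDM2-Nutlin", "MDM2-Pip2", "PDE2A"))

  pip2 <- p[["MDM2-Pip2"]]
  expect_equal(pip2$transient$hl_slow, 0.80)
  expect_equal(pip2$transient$a_slow, 3.6)
  expect_equal(pip2$transient$a_fast, 12)
  expect_equal(pip2$transient$hl_fast, 0.0057)

  expect_equal(p[["T4L"]]$transient$a_fast, 0)
  expect_false(is.finite(p[["T4L"]]$transient$hl_fast))

  for (preset in p) {
    expect_equal(preset$acv$total_var_mean / preset$total_var_ref, 1,
                 tolerance = 0.01)
    expect_equal(preset$acv$max_lag_index, preset$max_lag_ref)
  }

  # coarser discretization preserves the implied variance of a fixed-duration mean
  p4 <- abfe_presets(dt = 4 * 8e-4)
  expect_equal(p4[["MDM2-Pip2"]]$acv$total_var_mean * 4 / 41, 1,
               tolerance = 0.05)
})

test_that("dataset variants transform geometry and moments as specified", {
  acv <- autocov_model(0.5 * 2^(-(0:8) / 2), dt = 0.01)
  ens <- generate_ensemble(transient_model(0, Inf), acv, 20, 1000, seed = 55)

  sub <- make_variant(ens, "subsampled", k = 10)
  expect_equal(nrow(sub$values), 100)
  expect_equal(sub$dt, 0.1)

  blk <- make_variant(ens, "block_averaged", block = 100)
  expect_equal(nrow(blk$values), 10)
  expect_equal(blk$dt, 1)
  expect_equal(colMeans(blk$values), colMeans(ens$values), tolerance = 1e-12)

  sh <- make_variant(ens, "short", duration = 2)
  expect_equal(nrow(sh$values), 200)
  expect_equal(sh$dt, ens$dt)

  noisy <- make_variant(ens, "noisy", factor = sqrt(5))
  g0_ratio <- mean(apply(noisy$values, 2, acv_brute, lag = 0)) /
    mean(apply(ens$values, 2, acv_brute, lag = 0))
  expect_equal(g0_ratio, sqrt(5), tolerance = 1e-10)

  expect_error(make_variant(ens, "subsampled", k = 200), "< 10")
  expect_identical(make_variant(ens, "standard")$values, ens$values)
})

test_that("generator reports non-positive-definite targets instead of looping", {
  bad <- autocov_model(c(1, -0.9, 0.9, -0.9), dt = 1)
  expect_error(generate_ensemble(transient_model(0, Inf), bad, 2, 50),
               "positive definite")
})
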