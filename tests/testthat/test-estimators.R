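test_that("truncated sample mean matches hand values and validates n0", {
  expect_equal(sample_mean(sim_series(c(5, 5, 5, 5))), 5)
  expect_equal(sample_mean(sim_series(c(1, -1, 1, -1))), 0)
  expect_equal(sample_mean(sim_series(c(10, 0, 0, 0)), n0 = 1), 0)
  expect_error(sample_mean(sim_series(c(1, 2, 3)), n0 = 2), "n0")
  expect_error(sample_mean(sim_series(c(1, 2, 3)), n0 = -1), "n0")
})

test_that("autocovariance uses the truncated mean and divisor N at all lags", {
  s <- sim_series(c(1, -1, 1, -1))
  expect_equal(autocovariance(s)$gamma, c(1, -0.75, 0.5, -0.25))
  expect_equal(autocovariance(sim_series(c(0, 1, 0, 1)), max_lag = 1)$gamma,
               c(0.25, -0.1875))
  expect_equal(autocovariance(sim_series(rep(3, 10)))$gamma, rep(0, 10))
  expect_error(autocovariance(s, max_lag = 4), "max_lag")
})

test_that("autocovariance equals a brute-force double loop on short series", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:50, 1)
    s <- ar1_series(n, r = 0.5, seed = seed + 100)
    n0 <- sample(0:(n - 3), 1)
    ac <- autocovariance(s, n0 = n0)
    x <- s$values[(n0 + 1):n]
    for (lag in 0:(length(x) - 1)) {
      expect_equal(ac$gamma[lag + 1], acv_brute(x, lag), tolerance = 1e-12)
    }
  }
})

test_that("FFT and direct autocovariance paths agree", {
  s <- ar1_series(3000, r = 0.8, seed = 9)
  direct <- autocovariance(s, max_lag = 100)$gamma
  viafft <- truncsel:::acv_fft(s$values)[1:101]
  expect_equal(viafft, direct, tolerance = 1e-10)
})

test_that("paired sums, monotone rule, and convex minorant match hand values", {
  ac <- autocovariance(sim_series(c(1, -1, 1, -1)))
  expect_equal(gamma_pairs(ac)$Gamma, c(0.25, 0.25))
  gp3 <- structure(list(gamma = c(2, 1, 0.5)), class = "acv_sequence")
  expect_equal(gamma_pairs(gp3)$Gamma, 3) # trailing unpaired term dropped
  expect_equal(gamma_pairs(
    structure(list(gamma = rep(0, 6)), class = "acv_sequence"))$Gamma,
    rep(0, 3))

  mk <- function(G) structure(list(Gamma = G, M = length(G) - 1L),
                              class = "gamma_pairs")
  expect_equal(enforce_monotone(mk(c(3, 1, 0.5)))$Gamma, c(3, 1, 0.5))
  expect_equal(enforce_monotone(mk(c(3, 4, 1)))$Gamma, c(3, 3, 1))
  expect_equal(enforce_monotone(mk(1))$Gamma, 1)

  expect_equal(greatest_convex_minorant(mk(c(3, 1, 0.9)))$Gamma, c(3, 1, 0.9))
  expect_equal(greatest_convex_minorant(mk(c(3, 1, 0.99, 0.2)))$Gamma,
               c(3, 1, 0.6, 0.2))
  lin <- seq(5, 1, by = -1)
  expect_equal(greatest_convex_minorant(mk(lin))$Gamma, lin)
})

test_that("variance-of-mean hand examples hold", {
  s <- sim_series(c(1, -1, 1, -1))
  expect_equal(
    variance_of_mean(s, spec = estimator_spec("uncorrelated"))$var_mean, 0.25
  )
  expect_equal(
    variance_of_mean(s, spec = estimator_spec("initial_positive"))$var_mean, 0
  )
  const <- sim_series(rep(2.5, 30))
  for (spec in all_method_specs()) {
    expect_equal(variance_of_mean(const, spec = spec)$var_mean, 0)
  }
})

test_that("Geyer transforms only decrease the variance estimate", {
  for (seed in 1:8) {
    s <- ar1_series(300, r = 0.6, seed = seed)
    n0 <- (seed - 1) * 10
    vp <- variance_of_mean(s, n0, estimator_spec("initial_positive"))$var_mean
    vm <- variance_of_mean(s, n0, estimator_spec("initial_monotone"))$var_mean
    vc <- variance_of_mean(s, n0, estimator_spec("initial_convex"))$var_mean
    expect_gte(vp, vm)
    expect_gte(vm, vc)
  }
})

test_that("window estimates grow with window size when autocovariances are positive", {
  # smooth, strongly positively correlated series: all low-lag terms positive
  t <- seq(0, 4 * pi, length.out = 400)
  s <- sim_series(sin(t) + 2)
  sizes <- c(2L, 5L, 10L, 20L)
  g <- autocovariance(s, max_lag = max(sizes))$gamma
  expect_true(all(g[1:(max(sizes) + 1)] >= 0))
  v <- vapply(sizes, function(w) {
    variance_of_mean(s, spec = estimator_spec("window", window_size = w))$var_mean
  }, numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("estimates are nonnegative across methods and fixtures", {
  fixtures <- list(
    ar1_series(200, 0.7, seed = 1),
    ar1_series(200, 0.0, seed = 2),
    ar1_series(200, -0.4, seed = 3),
    sim_series(rep(1, 50))
  )
  for (s in fixtures) {
    g0 <- autocovariance(s, max_lag = 0)$gamma[1]
    for (spec in all_method_specs()[c("uncorrelated", "window5", "windowsqrt",
                                      "initial_positive", "initial_monotone",
                                      "initial_convex")]) {
      v <- variance_of_mean(s, spec = spec)$var_mean
      expect_gte(v, -1e-12 * g0)
    }
  }
})

test_that("ESS times the variance estimate recovers gamma_0 for every method", {
  s <- ar1_series(500, 0.5, seed = 4)
  g0 <- autocovariance(s, max_lag = 0)$gamma[1]
  for (spec in all_method_specs()) {
    est <- variance_of_mean(s, spec = spec)
    ess <- effective_sample_size(s, spec = spec)
    expect_equal(ess * est$var_mean, g0, tolerance = 1e-12)
  }
  # uncorrelated spec: ESS is exactly the retained length
  expect_equal(effective_sample_size(s, n0 = 17, estimator_spec("uncorrelated")),
               500 - 17)
  # degenerate series: variance 0, ESS undefined
  expect_true(is.na(effective_sample_size(sim_series(rep(1, 10)),
                                          spec = estimator_spec("uncorrelated"))))
})

test_that("ESS per sample approaches (1-r)/(1+r) for an AR(1) process", {
  r <- 0.5
  s <- ar1_series(100000, r, seed = 11)
  ess <- effective_sample_size(s, spec = estimator_spec("window",
                                                        window_size = "sqrt"))
  expect_equal(ess / length(s$values), (1 - r) / (1 + r), tolerance = 0.1)
})

test_that("triangular window agrees with overlapping batch means as N grows", {
  for (case in list(list(n = 500, b = 10), list(n = 2000, b = 10),
                    list(n = 2000, b = 40))) {
    s <- ar1_series(case$n, 0.6, seed = case$n + case$b)
    v <- variance_of_mean(
      s, spec = estimator_spec("window", window_size = case$b - 1L)
    )$var_mean
    o <- obm_var(s$values, case$b)
    expect_equal(v / o, 1, tolerance = 2 * case$b / case$n)
  }
})

test_that("window and nonoverlapping batch means agree in order of magnitude", {
  # the nonoverlapping estimator is a noisier cousin, kept as an oracle only
  s <- ar1_series(2000, 0.6, seed = 77)
  v <- variance_of_mean(s, spec = estimator_spec("window", window_size = 39L))$var_mean
  o <- nbm_var(s$values, 40)
  expect_gt(v / o, 0.4)
  expect_lt(v / o, 2.5)
})

test_that("estimator_spec validates window sizes", {
  expect_error(estimator_spec("window"), "window_size")
  expect_error(estimator_spec("window", window_size = 0), "window_size")
  expect_error(estimator_spec("window", window_size = 2.5), "window_size")
  expect_error(estimator_spec("uncorrelated", window_size = 5), "window")
  expect_silent(estimator_spec("window", window_size = "sqrt"))
})

test_that("smoothed-lag variant respects an externally supplied lag cap", {
  s <- ar1_series(600, 0.8, seed = 21)
  free <- variance_of_mean(s, spec = estimator_spec("smoothed_lag_convex"))
  capped <- variance_of_mean(s, spec = estimator_spec("smoothed_lag_convex"),
                             lag_cap = 5L)
  expect_lte(capped$max_lag_used, 5L)
  expect_lte(capped$max_lag_used, free$max_lag_used)
})
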