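# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (double loops, explicit batch means)
# so it cannot share a defect with the implementation it checks.

# Brute-force autocovariance at a single lag: explicit double-sum over pairs,
# divisor n, centered at the sample mean.
acv_brute <- function(x, lag) {
  n <- length(x)
  xb <- sum(x) / n
  total <- 0
  for (i in seq_len(n - lag)) {
    total <- total + (x[i] - xb) * (x[i + lag] - xb)
  }
  total / n
}

# Overlapping batch means estimate of Var(mean) at batch size b.
obm_var <- function(x, b) {
  n <- length(x)
  xb <- mean(x)
  k <- n - b + 1
  m <- vapply(seq_len(k), function(i) mean(x[i:(i + b - 1)]), numeric(1))
  sum((m - xb)^2) * b / (n * k)
}

# Nonoverlapping batch means estimate of Var(mean) at batch size b
# (requires b to divide length(x)).
nbm_var <- function(x, b) {
  n <- length(x)
  stopifnot(n %% b == 0)
  nb <- n %/% b
  m <- colMeans(matrix(x, b, nb))
  sum((m - mean(x))^2) / (nb * (nb - 1)) * 1 # sample variance of block means / nb
}

# AR(1) series with lag-1 correlation r, stationary start.
ar1_series <- function(n, r, seed, dt = 1) {
  set.seed(seed)
  e <- rnorm(n) * sqrt(1 - r^2)
  x <- as.numeric(stats::filter(e, r, method = "recursive",
                                init = rnorm(1)))
  sim_series(x, dt = dt)
}

# Exhaustive selector oracles over a selection curve.
oracle_min <- function(v) which(v == min(v))[1L]
oracle_llm <- function(v) {
  k <- length(v)
  for (j in seq_len(k)) {
    if ((j == 1L || v[j] <= v[j - 1L]) && (j == k || v[j] <= v[j + 1L])) {
      return(j)
    }
  }
  k
}

all_method_specs <- function() {
  list(
    uncorrelated = estimator_spec("uncorrelated"),
    window5 = estimator_spec("window", window_size = 5L),
    window50 = estimator_spec("window", window_size = 50L),
    windowsqrt = estimator_spec("window", window_size = "sqrt"),
    chodera = estimator_spec("chodera"),
    initial_positive = estimator_spec("initial_positive"),
    initial_monotone = estimator_spec("initial_monotone"),
    initial_convex = estimator_spec("initial_convex"),
    smoothed_lag_convex = estimator_spec("smoothed_lag_convex")
  )
}
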