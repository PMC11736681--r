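# Restore the caller's RNG state on exit so seeded helpers do not perturb
# the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ensemble error metrics for a set of truncated-mean estimates
#'
#' Decomposes the error of per-trajectory estimates against the known true
#' mean into bias and spread: `bias = mean(estimates) - true_mean`, `sd` is
#' the population standard deviation (divide by n, so that
#' `rmse^2 = bias^2 + sd^2` holds exactly), and
#' `rmse = sqrt(bias^2 + sd^2)`. 95% confidence intervals for each metric
#' come from a percentile bootstrap over resampled trajectories.
#'
#' @param estimates Numeric vector of per-trajectory estimates (>= 2).
#' @param true_mean The known true value.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param conf Confidence level for the percentile intervals (default 0.95).
#' @param seed Optional seed for the bootstrap resampling.
#' @return An `ensemble_metrics`: list with `rmse`, `bias`, `sd`, a `ci`
#'   list of length-2 intervals per metric, `n`, `n_boot`, `conf`, `seed`.
#' @examples
#' ensemble_metrics(c(1, -1), true_mean = 0, n_boot = 100)
#' @export
ensemble_metrics <- function(estimates, true_mean, n_boot = 10000L,
                             conf = 0.95, seed = NULL) {
  estimates <- as.numeric(estimates)
  n <- length(estimates)
  if (n < 2L) stop("need at least 2 estimates")
  bias <- mean(estimates) - true_mean
  s <- pop_sd(estimates)
  rmse <- sqrt(bias^2 + s^2)

  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    em <- matrix(estimates[idx], n_boot, n)
    mu <- rowMeans(em)
    b <- mu - true_mean
    v <- pmax(rowMeans(em^2) - mu^2, 0)
    list(bias = b, sd = sqrt(v), rmse = sqrt(b^2 + v))
  })
  alpha <- (1 - conf) / 2
  ci <- lapply(boot, stats::quantile, probs = c(alpha, 1 - alpha),
               names = FALSE)

  structure(
    list(rmse = rmse, bias = bias, sd = s, ci = ci, n = n,
         n_boot = as.integer(n_boot), conf = conf, seed = seed),
    class = "ensemble_metrics"
  )
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf(
    "<ensemble_metrics> n = %d: rmse %.4g [%.4g, %.4g], bias %.4g, sd %.4g\n",
    x$n, x$rmse, x$ci$rmse[1], x$ci$rmse[2], x$bias, x$sd
  ))
  invisible(x)
}

#' Evaluate a truncation heuristic on a synthetic ensemble
#'
#' Applies [select_truncation()] with the given estimator and mode to every
#' series, computes each truncated mean, and scores the set of means against
#' the ensemble's known true mean with [ensemble_metrics()]. The
#' distribution of discard times is returned alongside.
#'
#' @param ens A `synthetic_ensemble`.
#' @param spec An [estimator_spec()].
#' @param mode Selection mode (see [select_truncation()]).
#' @param exclude_fraction,stride Scan settings, see [selection_curve()].
#' @param n_boot,conf,seed Bootstrap settings, see [ensemble_metrics()].
#' @return A `heuristic_eval`: list with `metrics`, `discard_times` (ns),
#'   `n0` (per-series truncation indices), `means`, `spec`, `mode`.
#' @export
evaluate_heuristic <- function(ens, spec, mode = "min_mse",
                               exclude_fraction = 0.1, stride = 1L,
                               n_boot = 10000L, conf = 0.95, seed = NULL) {
  stopifnot(inherits(ens, "synthetic_ensemble"))
  ns <- n_series(ens)
  n0 <- integer(ns)
  means <- numeric(ns)
  for (j in seq_len(ns)) {
    sel <- select_truncation(ensemble_series(ens, j), spec, mode,
                             exclude_fraction, stride)
    n0[j] <- sel$n0_star
    means[j] <- sel$mean
  }
  metrics <- ensemble_metrics(means, ens$true_mean, n_boot, conf, seed)
  structure(
    list(
      metrics = metrics,
      discard_times = n0 * ens$dt,
      n0 = n0,
      means = means,
      spec = spec,
      mode = mode
    ),
    class = "heuristic_eval"
  )
}

#' @export
print.heuristic_eval <- function(x, ...) {
  qs <- stats::quantile(x$discard_times, c(0.25, 0.5, 0.75), names = FALSE)
  cat(sprintf(
    "<heuristic_eval> %s / %s: rmse %.4g, discard time quartiles %.3g/%.3g/%.3g ns\n",
    x$spec$method, x$mode, x$metrics$rmse, qs[1], qs[2], qs[3]
  ))
  invisible(x)
}

#' RMSE curve for fixed truncation points
#'
#' For every candidate truncation index on the scan grid, truncates *all*
#' series of the ensemble at that same fixed index and computes the RMSE of
#' the resulting means against the true mean. The minimizer is the optimal
#' fixed-time truncation point — the reference bound no heuristic can beat
#' beyond noise.
#'
#' @inheritParams evaluate_heuristic
#' @return A `fixed_truncation_curve`: data frame with columns `n0`, `time`,
#'   `rmse`; attributes `argmin` (row index), `n0_opt`, `rmse_opt`.
#' @export
fixed_truncation_curve <- function(ens, exclude_fraction = 0.1,
                                   stride = 1L) {
  stopifnot(inherits(ens, "synthetic_ensemble"))
  x <- ens$values
  n <- nrow(x)
  n0_max <- min(floor((1 - exclude_fraction) * n) - 1L, n - 2L)
  if (n0_max < 0) stop("candidate grid is empty for this ensemble")
  grid <- seq.int(0L, n0_max, by = as.integer(stride))
  # tail sums via reversed cumulative sums: rcs[i, j] = sum(x[i:n, j])
  rcs <- apply(x[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  rmse <- vapply(grid, function(n0) {
    m <- rcs[n0 + 1L, ] / (n - n0)
    sqrt(mean((m - ens$true_mean)^2))
  }, numeric(1))
  i <- which.min(rmse)
  structure(
    data.frame(n0 = grid, time = ens$t0 + grid * ens$dt, rmse = rmse),
    class = c("fixed_truncation_curve", "data.frame"),
    argmin = i, n0_opt = grid[i], rmse_opt = rmse[i]
  )
}

#' Metrics of a fixed truncation point applied to a whole ensemble
#'
#' Companion to [fixed_truncation_curve()]: full bias/SD/RMSE decomposition
#' with bootstrap intervals for one fixed `n0` applied uniformly.
#'
#' @inheritParams evaluate_heuristic
#' @param n0 Fixed truncation index applied to every series.
#' @return An [ensemble_metrics()] object.
#' @export
fixed_truncation_metrics <- function(ens, n0, n_boot = 10000L, conf = 0.95,
                                     seed = NULL) {
  n <- nrow(ens$values)
  means <- colMeans(ens$values[(n0 + 1):n, , drop = FALSE])
  ensemble_metrics(means, ens$true_mean, n_boot, conf, seed)
}

#' Confidence-interval coverage of the true mean after truncation
#'
#' For each series: select a truncation point, form the interval
#' `mean +/- z * sqrt(Var(mean))` with `z` the two-sided normal quantile for
#' `level`, and record whether it contains the true mean. Because the rule
#' minimizes the estimated standard error, coverage is expected to fall
#' below nominal for strongly correlated data.
#'
#' @inheritParams evaluate_heuristic
#' @param level Nominal confidence level in (0, 1]; default 0.95.
#' @return The coverage fraction in `[0, 1]`.
#' @export
ci_coverage <- function(ens, spec, mode = "min_mse", level = 0.95,
                        exclude_fraction = 0.1, stride = 1L) {
  stopifnot(inherits(ens, "synthetic_ensemble"))
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level >= 1) {
    stop("level must be in [0, 1)")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ns <- n_series(ens)
  covered <- logical(ns)
  for (j in seq_len(ns)) {
    sel <- select_truncation(ensemble_series(ens, j), spec, mode,
                             exclude_fraction, stride)
    half <- z * sqrt(sel$var_mean)
    covered[j] <- abs(sel$mean - ens$true_mean) <= half
  }
  mean(covered)
}

# Exact variance of the mean of n equally weighted samples of a unit-variance
# stationary process with autocorrelation rho_t = exp(log_r * t):
# V = (1/n) * (1 + 2 * sum_{t=1}^{n-1} (1 - t/n) * r^t), via geometric sums.
ar1_var_mean <- function(n, log_r) {
  if (n == 1L) return(1)
  r <- exp(log_r)
  omr <- -expm1(log_r) # 1 - r, accurately
  rn1 <- exp((n - 1) * log_r)
  rn <- exp(n * log_r)
  s1 <- r * (1 - rn1) / omr
  s2 <- r * (1 - n * rn1 + (n - 1) * rn) / omr^2
  (1 + 2 * (s1 - s2 / n)) / n
}

#' Variance inflation caused by subsampling a correlated series
#'
#' For a stationary series whose autocorrelation decays as a pure base-2
#' exponential with the given half-life (in samples), computes the ratio
#' `Var(mean of the series subsampled every g samples) / Var(mean of the
#' full series)`, where `g = (1 + r) / (1 - r)` (rounded to an integer) is
#' the statistical inefficiency and `r = 2^(-1 / half_life)` is the lag-1
#' autocorrelation. In the long-half-life, long-series limit the ratio tends
#' to `coth(1)`, i.e. a 31% variance increase — the penalty for discarding
#' partially informative samples.
#'
#' `"analytic"` mode uses closed-form geometric sums for both variances;
#' `"simulated"` mode estimates them over a seeded ensemble of AR(1) series.
#'
#' @param half_life Autocorrelation half-life in samples (> 0).
#' @param n_points Series length.
#' @param mode `"analytic"` or `"simulated"`.
#' @param n_series Ensemble size for simulated mode (default 200).
#' @param seed Seed for simulated mode.
#' @return A list with `ratio`, `pct_increase` (`100 * (ratio - 1)`), `g`
#'   (the integer subsampling interval), `r`, `n_sub` (subsampled length),
#'   and `mode`.
#' @examples
#' subsampling_inflation(10, 10000)$ratio
#' @export
subsampling_inflation <- function(half_life, n_points,
                                  mode = c("analytic", "simulated"),
                                  n_series = 200L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(half_life > 0, n_points >= 2)
  n <- as.integer(n_points)
  log_r <- -log(2) / half_life
  r <- exp(log_r)
  omr <- -expm1(log_r)
  g <- max(1L, as.integer(round((1 + r) / omr)))
  m <- as.integer(floor((n - 1) / g)) + 1L

  if (mode == "analytic") {
    ratio <- ar1_var_mean(m, g * log_r) / ar1_var_mean(n, log_r)
  } else {
    sd_innov <- sqrt(-expm1(2 * log_r))
    ratio <- with_seed(seed, {
      mf <- ms <- numeric(n_series)
      sub_idx <- seq.int(1L, n, by = g)
      for (i in seq_len(n_series)) {
        e <- stats::rnorm(n) * sd_innov
        x <- as.numeric(stats::filter(e, r, method = "recursive",
                                      init = stats::rnorm(1)))
        mf[i] <- mean(x)
        ms[i] <- mean(x[sub_idx])
      }
      stats::var(ms) / stats::var(mf)
    })
  }
  list(ratio = ratio, pct_increase = 100 * (ratio - 1), g = g, r = r,
       n_sub = m, mode = mode)
}
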