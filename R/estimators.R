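#' Specify a variance-of-the-mean estimator
#'
#' The generalized marginal-standard-error rule is parameterized by how the
#' variance of the truncated mean is estimated. The available methods span a
#' spectrum of how completely autocorrelation is accounted for:
#'
#' * `"uncorrelated"`: `gamma_0 / N`, ignoring all autocorrelation (the
#'   classical rule).
#' * `"window"`: a triangular (Bartlett-type) lag window of size
#'   `window_size`; the special value `"sqrt"` uses `floor(sqrt(N))`,
#'   recomputed for every candidate truncation point.
#' * `"initial_positive"`, `"initial_monotone"`, `"initial_convex"`: Geyer's
#'   initial-sequence estimators, which terminate and regularize the sequence
#'   of paired autocovariances `Gamma_m = gamma_{2m} + gamma_{2m+1}`.
#' * `"chodera"`: truncate the plain autocovariance sum at the first
#'   nonpositive term.
#' * `"smoothed_lag_convex"`: the initial-convex estimator with the extra
#'   constraint that the maximum lag never increases between successive
#'   truncation points of a selection scan.
#'
#' @param method One of the method names above.
#' @param window_size Positive integer window size, or `"sqrt"`. Required for
#'   (and only for) `method = "window"`.
#' @return An object of class `estimator_spec`.
#' @examples
#' estimator_spec("window", window_size = "sqrt")
#' estimator_spec("initial_convex")
#' @export
estimator_spec <- function(method = c(
                             "uncorrelated", "window", "initial_positive",
                             "initial_monotone", "initial_convex", "chodera",
                             "smoothed_lag_convex"
                           ),
                           window_size = NULL) {
  method <- match.arg(method)
  if (method == "window") {
    if (is.null(window_size)) {
      stop("window_size is required for method = \"window\"")
    }
    if (!(identical(window_size, "sqrt") ||
          (is.numeric(window_size) && length(window_size) == 1L &&
           is.finite(window_size) && window_size >= 1 &&
           window_size == as.integer(window_size)))) {
      stop("window_size must be a positive integer or \"sqrt\"")
    }
  } else if (!is.null(window_size)) {
    stop("window_size is only meaningful for method = \"window\"")
  }
  structure(list(method = method, window_size = window_size),
            class = "estimator_spec")
}

#' @export
print.estimator_spec <- function(x, ...) {
  ws <- if (is.null(x$window_size)) "" else paste0(" (s = ", x$window_size, ")")
  cat("<estimator_spec> ", x$method, ws, "\n", sep = "")
  invisible(x)
}

#' Autocovariance of a truncated series
#'
#' Estimates `gamma_t` for lags `t = 0, ..., max_lag` on the samples retained
#' after discarding the first `n0`. The convention is deliberately
#' uncorrected: deviations are taken from the truncated-sample mean and every
#' lag is divided by the number of retained samples `N` (not `N - t`), so the
#' terms can be summed directly into a variance-of-the-mean estimate.
#'
#' @param series A [sim_series()].
#' @param n0 Number of leading samples to discard.
#' @param max_lag Largest lag to compute; defaults to `N - 1` where `N` is
#'   the number of retained samples.
#' @return An `acv_sequence`: list with `gamma` (length `max_lag + 1`), `n0`,
#'   and `n_used`.
#' @export
autocovariance <- function(series, n0 = 0L, max_lag = NULL) {
  x <- series_tail(series, n0)
  n_used <- length(x)
  if (is.null(max_lag)) max_lag <- n_used - 1L
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 0 ||
      max_lag != as.integer(max_lag)) {
    stop("max_lag must be a nonnegative integer")
  }
  if (max_lag > n_used - 1L) {
    stop("max_lag (", max_lag, ") cannot exceed N - 1 = ", n_used - 1L)
  }
  gamma <- cpp_acv(x, as.integer(max_lag))
  structure(list(gamma = gamma, n0 = n0, n_used = n_used),
            class = "acv_sequence")
}

#' Pairwise sums of autocovariance terms
#'
#' Forms `Gamma_m = gamma_{2m} + gamma_{2m+1}`, the paired sequence used by
#' the initial-sequence estimators. For reversible chains the true `Gamma`
#' sequence is positive, decreasing, and convex, which is what the
#' regularization rules exploit. A trailing unpaired autocovariance term is
#' dropped.
#'
#' @param ac An `acv_sequence` from [autocovariance()] with at least 2 lags.
#' @return A `gamma_pairs` object: list with `Gamma` and `M` (last index,
#'   0-based).
#' @export
gamma_pairs <- function(ac) {
  g <- ac$gamma
  if (length(g) < 2L) stop("need at least 2 autocovariance lags to form pairs")
  n_pairs <- length(g) %/% 2L
  idx <- seq_len(n_pairs)
  Gamma <- g[2L * idx - 1L] + g[2L * idx]
  structure(list(Gamma = Gamma, M = n_pairs - 1L), class = "gamma_pairs")
}

# Positive rule: keep pairs strictly before the first nonpositive Gamma
# (first-violation stopping). Returns an empty sequence if Gamma_0 <= 0.
positive_rule <- function(gp) {
  G <- gp$Gamma
  bad <- which(G <= 0)
  if (length(bad)) G <- G[seq_len(bad[1L] - 1L)]
  structure(list(Gamma = G, M = length(G) - 1L), class = "gamma_pairs")
}

#' Monotone rule for a paired autocovariance sequence
#'
#' Replaces the sequence by its running minimum, enforcing that it is
#' nonincreasing. Expects the positive rule to have been applied already.
#'
#' @param gp A `gamma_pairs` object.
#' @return A `gamma_pairs` object of the same length.
#' @export
enforce_monotone <- function(gp) {
  structure(list(Gamma = cummin(gp$Gamma), M = gp$M), class = "gamma_pairs")
}

#' Greatest convex minorant of a paired autocovariance sequence
#'
#' Replaces the (already positive and nonincreasing) sequence by the greatest
#' convex function lying at or below it, evaluated at the integer indices:
#' the lower convex hull of the points `(m, Gamma_m)`.
#'
#' @param gp A `gamma_pairs` object, monotone rule already applied.
#' @return A `gamma_pairs` object of the same length.
#' @export
greatest_convex_minorant <- function(gp) {
  y <- gp$Gamma
  n <- length(y)
  if (n <= 2L) return(gp)
  x <- seq_len(n) - 1
  # lower convex hull by monotone scan; hull holds indices into x/y
  hull <- c(1L, 2L)
  for (i in 3:n) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # pop b if it lies on or above the chord a--i
      if ((y[i] - y[a]) * (x[b] - x[a]) <= (y[b] - y[a]) * (x[i] - x[a])) {
        hull <- hull[-length(hull)]
      } else {
        break
      }
    }
    hull <- c(hull, i)
  }
  out <- stats::approx(x[hull], y[hull], xout = x)$y
  structure(list(Gamma = out, M = gp$M), class = "gamma_pairs")
}

# Full-lag autocovariance via FFT (O(N log N)); identical convention to
# cpp_acv. Used by the scanning estimators on long series, where computing
# lags until the termination rule fires would otherwise cost O(N * lag).
acv_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(xc, numeric(m - n)))
  s <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / m
  s[seq_len(n)] / n
}

# Autocovariance lags until the first nonpositive lag >= 1 (inclusive).
# Short series and quickly-terminating (weakly correlated) cases use the
# direct C++ scan; otherwise the full FFT transform is cheaper.
acv_until_first_nonpos <- function(x, lag_cap) {
  n <- length(x)
  probe <- min(lag_cap, 64L)
  g <- cpp_acv_first_nonpos(x, probe)
  if (g[length(g)] <= 0 || length(g) == lag_cap + 1L) return(g)
  if (n < 2048L) return(cpp_acv_first_nonpos(x, lag_cap))
  g <- acv_fft(x)
  bad <- which(g[-1L] <= 0)
  last <- if (length(bad)) bad[1L] + 1L else n
  g[seq_len(min(last, lag_cap + 1L))]
}

# Autocovariance lags in complete pairs until the first nonpositive pair sum
# (inclusive), capped at pair index pair_cap.
acv_until_nonpos_pair <- function(x, pair_cap) {
  n <- length(x)
  probe <- min(pair_cap, 32L)
  g <- cpp_acv_gamma_pairs(x, probe)
  np <- length(g) %/% 2L
  if (np > 0L) {
    terminated <- g[2L * np - 1L] + g[2L * np] <= 0
    if (terminated || np == pair_cap + 1L || 2L * np + 1L > n - 1L) return(g)
  }
  if (n < 2048L) return(cpp_acv_gamma_pairs(x, pair_cap))
  g <- acv_fft(x)
  n_pairs <- min(pair_cap + 1L, length(g) %/% 2L)
  idx <- seq_len(n_pairs)
  Gamma <- g[2L * idx - 1L] + g[2L * idx]
  bad <- which(Gamma <= 0)
  keep <- if (length(bad)) bad[1L] else n_pairs
  g[seq_len(2L * keep)]
}

# Shared early exit: a constant series has zero autocovariance at every lag,
# so every estimator returns 0 rather than failing.
is_degenerate <- function(x) {
  r <- range(x)
  r[2] - r[1] == 0
}

#' Estimate the variance of the truncated mean
#'
#' The quantity whose square root the generalized marginal-standard-error
#' rule minimizes. All methods share the autocovariance convention of
#' [autocovariance()] and differ only in which lags enter the sum and with
#' what weight; see [estimator_spec()] for the roster.
#'
#' Dispatch, writing `N` for the retained length and `g_t` for `gamma_t`:
#' * uncorrelated: `g_0 / N`.
#' * window of size `s`: `(g_0 + 2 * sum_{t=1}^{s_eff} (1 - t/(s+1)) g_t) / N`
#'   with `s_eff = min(s, N - 1)`; `s = floor(sqrt(N))` for `"sqrt"`.
#' * initial_*: `(-g_0 + 2 * sum_{m=0}^{M} Gamma_m) / N` after the positive
#'   rule (stop before the first nonpositive `Gamma`) and then the monotone
#'   and/or convex transforms.
#' * chodera: `(g_0 + 2 * sum_{t=1}^{T-1} g_t) / N` where `T` is the first
#'   lag with `g_T <= 0`.
#' * smoothed_lag_convex: initial_convex with the pair sequence additionally
#'   capped at `lag_cap`; its `max_lag_used` is meant to be threaded into the
#'   next call of a scan so caps never increase.
#'
#' @param series A [sim_series()].
#' @param n0 Number of leading samples to discard (must leave >= 2).
#' @param spec An [estimator_spec()].
#' @param lag_cap Optional largest autocovariance lag allowed, used by
#'   `smoothed_lag_convex` to carry the previous truncation point's maximum
#'   lag forward.
#' @return A `vom_estimate`: list with `var_mean`, `max_lag_used`, `spec`,
#'   `gamma0` and `n_used`.
#' @export
variance_of_mean <- function(series, n0 = 0L, spec, lag_cap = NULL) {
  stopifnot(inherits(spec, "estimator_spec"))
  x <- series_tail(series, n0)
  n <- length(x)
  if (is_degenerate(x)) {
    return(structure(
      list(var_mean = 0, max_lag_used = 0L, spec = spec, gamma0 = 0,
           n_used = n),
      class = "vom_estimate"
    ))
  }

  method <- spec$method
  if (method == "uncorrelated") {
    g <- cpp_acv(x, 0L)
    v <- g[1L] / n
    used <- 0L
  } else if (method == "window") {
    s <- spec$window_size
    if (identical(s, "sqrt")) s <- floor(sqrt(n))
    s <- as.integer(s)
    s_eff <- min(s, n - 1L)
    g <- cpp_acv(x, s_eff)
    w <- 1 - seq_len(s_eff) / (s + 1)
    v <- (g[1L] + 2 * sum(w * g[-1L])) / n
    used <- s_eff
  } else if (method == "chodera") {
    g <- acv_until_first_nonpos(x, n - 1L)
    pos <- g[-1L]
    if (length(pos) && pos[length(pos)] <= 0) pos <- pos[-length(pos)]
    v <- (g[1L] + 2 * sum(pos)) / n
    used <- length(pos)
  } else {
    # Geyer initial-sequence family
    pair_cap <- (n - 2L) %/% 2L
    if (method == "smoothed_lag_convex" && !is.null(lag_cap)) {
      pair_cap <- min(pair_cap, max(0L, as.integer(lag_cap) %/% 2L))
    }
    g <- acv_until_nonpos_pair(x, pair_cap)
    g0 <- g[1L]
    gp <- positive_rule(gamma_pairs(
      structure(list(gamma = g), class = "acv_sequence")
    ))
    if (method %in% c("initial_monotone", "initial_convex",
                      "smoothed_lag_convex")) {
      gp <- enforce_monotone(gp)
    }
    if (method %in% c("initial_convex", "smoothed_lag_convex")) {
      gp <- greatest_convex_minorant(gp)
    }
    v <- (-g0 + 2 * sum(gp$Gamma)) / n
    used <- if (length(gp$Gamma)) 2L * (length(gp$Gamma) - 1L) + 1L else 0L
    g <- g[1L] # report gamma0 below
  }

  gamma0 <- g[1L]
  if (v < 0) {
    if (v >= -1e-12 * gamma0) {
      v <- 0
    } else {
      stop("internal error: negative variance-of-mean estimate (", v,
           ") beyond tolerance for method ", method)
    }
  }
  structure(
    list(var_mean = v, max_lag_used = used, spec = spec, gamma0 = gamma0,
         n_used = n),
    class = "vom_estimate"
  )
}

#' Effective sample size of a truncated series
#'
#' `ESS = gamma_0 / Var(mean)`: the number of equivalent independent samples
#' implied by a variance-of-the-mean estimate. Equals the retained length
#' exactly under the uncorrelated estimator, and shrinks as the estimator
#' accounts for more positive autocorrelation.
#'
#' @inheritParams variance_of_mean
#' @return The effective sample size, or `NA_real_` when the variance
#'   estimate is zero (degenerate series) and the ESS is undefined.
#' @export
effective_sample_size <- function(series, n0 = 0L, spec) {
  est <- variance_of_mean(series, n0, spec)
  if (est$var_mean == 0) return(NA_real_)
  est$gamma0 / est$var_mean
}
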