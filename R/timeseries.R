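#' Construct a simulation time series
#'
#' A `sim_series` is an ordered set of scalar samples taken at a uniform
#' sampling interval, the object all truncation-point machinery acts on.
#' Values are typically an observable trace such as a free-energy estimate in
#' kcal/mol sampled every `dt` nanoseconds.
#'
#' @param values Numeric vector of at least two finite samples.
#' @param dt Sampling interval (ns), a single positive number.
#' @param t0 Time of the first sample (ns). Defaults to 0.
#'
#' @return An object of class `sim_series` with fields `values`, `dt`, `t0`.
#' @examples
#' s <- sim_series(rnorm(100), dt = 0.1)
#' sample_mean(s, n0 = 10)
#' @export
sim_series <- function(values, dt = 1, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a sim_series needs at least 2 samples, got ", length(values))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop("non-finite value at sample ", bad)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number")
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("t0 must be a single finite number")
  }
  structure(list(values = values, dt = dt, t0 = t0), class = "sim_series")
}

#' @export
print.sim_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<sim_series> %d samples, dt = %g ns, t = [%g, %g] ns\n",
    n, x$dt, x$t0, x$t0 + (n - 1) * x$dt
  ))
  cat(sprintf(
    "  mean %.6g, sd %.6g\n", mean(x$values), stats::sd(x$values)
  ))
  invisible(x)
}

#' @export
length.sim_series <- function(x) length(x$values)

# Time stamps of every sample.
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) * series$dt
}

# Retained tail after discarding the first n0 samples; validates n0.
series_tail <- function(series, n0, min_keep = 2L) {
  n <- length(series$values)
  if (length(n0) != 1L || is.na(n0) || n0 != as.integer(n0) || n0 < 0 ||
      n0 > n - min_keep) {
    stop("n0 must be an integer in [0, ", n - min_keep, "], got ", n0)
  }
  series$values[(n0 + 1):n]
}

#' Mean of the truncated series
#'
#' Arithmetic mean of the samples retained after discarding the first `n0`
#' samples (so `n0 = 0` averages the whole series).
#'
#' @param series A [sim_series()].
#' @param n0 Number of leading samples to discard (0-based truncation index).
#' @return The truncated sample mean.
#' @export
sample_mean <- function(series, n0 = 0L) {
  mean(series_tail(series, n0))
}
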