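#' Biexponential initial-transient model
#'
#' Describes the deterministic decay of a series toward its stationary mean
#' as the sum of a slow and an optional fast exponential, parameterized by
#' half-lives (base-2 exponentials): `a_slow * 2^(-t/hl_slow) + a_fast *
#' 2^(-t/hl_fast)`. A half-life of `Inf` together with a zero
#' pre-exponential factor denotes an absent term.
#'
#' @param a_slow Slow pre-exponential factor (observable units, kcal/mol).
#' @param hl_slow Slow half-life (ns), > 0 (may be `Inf`).
#' @param a_fast Fast pre-exponential factor; 0 when the fast term is absent
#'   or was rejected by the fit.
#' @param hl_fast Fast half-life (ns), > 0 (may be `Inf`).
#' @return A `transient_model` object.
#' @export
transient_model <- function(a_slow, hl_slow, a_fast = 0, hl_fast = Inf) {
  if (!(hl_slow > 0) || !(hl_fast > 0)) stop("half-lives must be positive")
  structure(
    list(a_slow = a_slow, hl_slow = hl_slow, a_fast = a_fast,
         hl_fast = hl_fast),
    class = "transient_model"
  )
}

#' Evaluate a transient model on a time grid
#'
#' @param model A [transient_model()].
#' @param t Times (ns) at which to evaluate the decay.
#' @return Numeric vector of transient values.
#' @export
transient_values <- function(model, t) {
  term <- function(a, hl) {
    if (a == 0) return(numeric(length(t)))
    a * 2^(-t / hl)
  }
  term(model$a_slow, model$hl_slow) + term(model$a_fast, model$hl_fast)
}

#' Discretized autocovariance model
#'
#' Holds autocovariance values per integer lag at a fixed sampling interval,
#' truncated to zero beyond `max_lag_index`. The implied "total variance of
#' the mean" is the lag sum from `-max_lag_index` to `+max_lag_index`, i.e.
#' `gamma_0 + 2 * sum(gamma_t)`.
#'
#' @param gamma Autocovariance values for lags `0, 1, ..., max_lag_index`
#'   (squared observable units).
#' @param dt Sampling interval (ns) the lags refer to.
#' @return An `autocov_model` with fields `gamma`, `dt`, `max_lag_index`,
#'   `total_var_mean`.
#' @export
autocov_model <- function(gamma, dt) {
  gamma <- as.numeric(gamma)
  if (!length(gamma) || !all(is.finite(gamma))) {
    stop("gamma must be a nonempty finite numeric vector")
  }
  if (gamma[1L] < 0) stop("gamma[0] must be nonnegative")
  # trim trailing zeros; keep at least lag 0
  nz <- which(gamma != 0)
  last <- if (length(nz)) max(nz) else 1L
  gamma <- gamma[seq_len(max(last, 1L))]
  structure(
    list(
      gamma = gamma, dt = dt, max_lag_index = length(gamma) - 1L,
      total_var_mean = gamma[1L] + 2 * sum(gamma[-1L])
    ),
    class = "autocov_model"
  )
}

#' Fit a biexponential initial transient
#'
#' Fits the head of a series with a single base-2 exponential decay toward a
#' stationary baseline, then fits the residual with a second, shorter
#' half-life exponential. The fast term is retained only if its
#' pre-exponential factor comes out positive; when both terms are retained
#' the parameters are polished with a joint four-parameter fit. The baseline
#' is the mean of the samples at and beyond `baseline_start`, mirroring the
#' practice of taking the "true" mean from the stationary tail of a long
#' run.
#'
#' @param series A [sim_series()].
#' @param window Duration (ns, from the first sample) of the head used for
#'   the transient fits. Default 10 ns.
#' @param baseline_start Time offset (ns) from the first sample at which the
#'   stationary baseline region starts. Defaults to `window`.
#' @param baseline Optional known baseline value, overriding the tail mean.
#' @return A [transient_model()]. Flat data yield `a_slow = 0` rather than
#'   an error.
#' @export
fit_transient <- function(series, window = 10, baseline_start = window,
                          baseline = NULL) {
  t_rel <- series_times(series) - series$t0
  dur <- t_rel[length(t_rel)]
  if (window > dur) stop("window (", window, " ns) exceeds series duration")
  if (is.null(baseline)) {
    tail_idx <- t_rel >= baseline_start
    if (!any(tail_idx)) stop("no samples at or beyond baseline_start")
    baseline <- mean(series$values[tail_idx])
  }
  head_idx <- t_rel < window
  th <- t_rel[head_idx]
  y <- series$values[head_idx] - baseline
  scale <- max(abs(y))
  if (scale == 0 || scale < 1e-12 * max(abs(series$values), 1)) {
    return(transient_model(0, Inf))
  }

  half_life_guess <- function(tt, yy, fallback) {
    # log-linear slope on the same-signed, non-negligible part of the decay
    keep <- abs(yy) > 1e-3 * max(abs(yy)) & sign(yy) == sign(yy[1L])
    if (sum(keep) < 3L) return(fallback)
    fit <- stats::lm(log2(abs(yy[keep])) ~ tt[keep])
    sl <- stats::coef(fit)[2L]
    if (!is.finite(sl) || sl >= 0) fallback else as.numeric(-1 / sl)
  }

  fit_exp <- function(tt, yy, a0, h0) {
    d <- data.frame(tt = tt, yy = yy)
    minpack.lm::nlsLM(
      yy ~ a * 2^(-tt / h),
      data = d, start = list(a = a0, h = h0),
      lower = c(a = -Inf, h = series$dt / 100),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }

  h0 <- half_life_guess(th, y, fallback = window / 5)
  slow <- fit_exp(th, y, a0 = y[1L], h0 = h0)
  a_s <- stats::coef(slow)[["a"]]
  h_s <- stats::coef(slow)[["h"]]

  resid <- y - stats::predict(slow)
  fast <- tryCatch(
    fit_exp(th, resid, a0 = resid[1L], h0 = max(h_s / 50, 2 * series$dt)),
    error = function(e) NULL
  )
  a_f <- if (is.null(fast)) 0 else stats::coef(fast)[["a"]]
  h_f <- if (is.null(fast)) Inf else stats::coef(fast)[["h"]]

  if (a_f > 0 && h_f < h_s) {
    # joint polish of both terms from the sequential starting point
    d <- data.frame(tt = th, yy = y)
    joint <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ a * 2^(-tt / h) + af * 2^(-tt / hf),
        data = d,
        start = list(a = a_s, h = h_s, af = a_f, hf = h_f),
        lower = c(a = -Inf, h = series$dt / 100, af = -Inf,
                  hf = series$dt / 100),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(joint)) {
      cf <- stats::coef(joint)
      if (cf[["af"]] > 0 && cf[["hf"]] < cf[["h"]]) {
        return(transient_model(cf[["a"]], cf[["h"]], cf[["af"]], cf[["hf"]]))
      }
    }
  }
  transient_model(a_s, h_s)
}

#' Fit a per-lag autocovariance model to a stationary series
#'
#' The first two lags are computed directly from the series. Later lags are
#' reconstructed from the initial-convex paired sequence: the positive,
#' monotone and convex rules are applied to `Gamma_m = gamma_{2m} +
#' gamma_{2m+1}`, the resulting convex sequence is interpolated linearly in
#' the pair index, and each interpolated pair value is split evenly across
#' its two lags (so consecutive lag pairs still sum back to `Gamma`). Lags
#' beyond the convex sequence's termination are zero, and that termination
#' defines `max_lag_index`.
#'
#' The caller is responsible for passing an approximately stationary series
#' (e.g. the tail of a long run with the transient excluded).
#'
#' @param series A [sim_series()].
#' @return An [autocov_model()] at the series' sampling interval.
#' @export
fit_autocov_model <- function(series) {
  x <- series$values
  n <- length(x)
  if (n < 4L) stop("series too short to form any autocovariance pair")
  if (is_degenerate(x)) {
    stop("constant series: zero-variance autocovariance model is degenerate")
  }
  g <- cpp_acv_gamma_pairs(x, (n - 2L) %/% 2L)
  gp <- positive_rule(gamma_pairs(
    structure(list(gamma = g), class = "acv_sequence")
  ))
  if (gp$M < 0L) stop("no positive autocovariance pair; cannot fit model")
  gc <- greatest_convex_minorant(enforce_monotone(gp))
  G <- gc$Gamma
  M <- length(G) - 1L

  max_lag <- 2L * M + 1L
  gamma <- numeric(max_lag + 1L)
  gamma[1:2] <- g[1:2]
  if (max_lag >= 2L) {
    lags <- 2:max_lag
    # pair-index positions of each lag; clamp to the fitted range
    pos <- pmin(pmax((lags - 0.5) / 2, 0), M)
    Gi <- if (M == 0L) rep(G, length(pos)) else {
      stats::approx(0:M, G, xout = pos)$y
    }
    gamma[lags + 1L] <- Gi / 2
  }
  autocov_model(gamma, series$dt)
}

# Parameters fitted to the bound-leg (ligand-vanish) stages of five long
# absolute binding free energy calculations: slow/fast transient terms, the
# total variance of the mean implied by the initial-convex autocovariance
# series, and the index at which that series terminates, all at the native
# 0.8 ps sampling interval.
abfe_preset_table <- function() {
  data.frame(
    name = c("T4L", "MIF", "MDM2-Nutlin", "MDM2-Pip2", "PDE2A"),
    hl_slow = c(0.33, 0.88, 1.6, 0.80, 0.33),
    a_slow = c(0.86, 4.7, 2.6, 3.6, 13),
    hl_fast = c(Inf, 0.0040, 0.0052, 0.0057, 0.019),
    a_fast = c(0, 14, 21, 12, 13),
    total_var = c(110, 55, 81, 41, 520),
    max_lag = c(7175, 749, 577, 335, 1699),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-model presets for absolute binding free energy systems
#'
#' Five named presets (T4L, MIF, MDM2-Nutlin, MDM2-Pip2, PDE2A) modeled on
#' the ligand-vanish stage of long absolute binding free energy
#' calculations. Each preset pairs a fitted biexponential transient with a
#' *surrogate* autocovariance function: only summary descriptors of the real
#' autocovariances are available (total variance of the mean and the maximum
#' lag index of the initial-convex series), so the surrogate is a
#' two-component decay — a fast component with the fast transient's
#' half-life and an exponential tail reaching 1% of its initial value at the
#' maximum lag — with equal lag-0 split, scaled so the lag sum from `-L` to
#' `+L` reproduces the recorded total variance at the native 0.8 ps
#' interval. The surrogate is an explicit stand-in and is not claimed to
#' match the originally fitted autocovariance functions.
#'
#' The surrogate is a continuous function of the time lag, so presets can be
#' discretized at a coarser `dt`: the maximum lag index and the discrete lag
#' sum then scale so the implied variance of the mean of a fixed-duration
#' series is approximately unchanged.
#'
#' @param dt Sampling interval (ns) at which to discretize the surrogate
#'   autocovariance. Default 8e-4 ns (0.8 ps), the native interval.
#' @return A named list of presets, each a list with `name`, `transient`
#'   (a [transient_model()]), `acv` (an [autocov_model()]), and the recorded
#'   `total_var_ref` and `max_lag_ref` at the native interval.
#' @examples
#' p <- abfe_presets()
#' p[["MDM2-Pip2"]]$transient$hl_slow # 0.80 ns
#' @export
abfe_presets <- function(dt = 8e-4) {
  dt0 <- 8e-4
  tab <- abfe_preset_table()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    trans <- transient_model(row$a_slow, row$hl_slow, row$a_fast, row$hl_fast)
    # surrogate autocovariance: fast component + exponential tail
    h_tail <- row$max_lag * dt0 / log2(100)
    h_fast <- if (is.finite(row$hl_fast)) max(row$hl_fast, 2 * dt0)
              else 2 * dt0
    L <- max(1L, as.integer(round(row$max_lag * dt0 / dt)))
    target <- row$total_var * dt0 / dt
    lag_t <- (0:L) * dt
    comp_fast <- 2^(-lag_t / h_fast)
    comp_tail <- 2^(-lag_t / h_tail)
    shape <- comp_fast + comp_tail
    denom <- shape[1L] + 2 * sum(shape[-1L])
    gamma <- (target / denom) * shape
    list(
      name = row$name,
      transient = trans,
      acv = autocov_model(gamma, dt),
      total_var_ref = row$total_var,
      max_lag_ref = row$max_lag
    )
  })
  names(out) <- tab$name
  out
}

#' Generate an ensemble of correlated synthetic time series
#'
#' Each series is built by drawing standard-normal noise, multiplying by the
#' lower Cholesky factor of the symmetric banded matrix with entries
#' `gamma(|i - j|)` (reintroducing the prescribed autocovariance), and
#' adding the deterministic transient. The stationary part has true mean 0
#' by construction, so the ensemble's true mean is exactly known.
#'
#' The target matrix is banded at the autocovariance model's maximum lag. A
#' truncated empirical autocovariance need not be positive semidefinite, so
#' an escalating diagonal jitter (starting at `1e-10 * gamma_0`, growing
#' tenfold up to `1e-4 * gamma_0`) is applied before the factorization is
#' declared failed.
#'
#' Randomness uses one root seed from which per-series child seeds are
#' drawn, so an ensemble can be extended without reshuffling existing
#' members.
#'
#' @param transient A [transient_model()] (use `transient_model(0, Inf)` for
#'   none).
#' @param acv An [autocov_model()].
#' @param n_series Number of series to generate.
#' @param n_points Samples per series.
#' @param dt Sampling interval; must match `acv$dt` (default).
#' @param seed Root RNG seed. Drawn randomly when `NULL`.
#' @return A `synthetic_ensemble`: list with `values` (an
#'   `n_points x n_series` matrix), `dt`, `t0`, `true_mean` (0), `transient`,
#'   `acv`, `seed`, `variant`.
#' @export
generate_ensemble <- function(transient, acv, n_series, n_points,
                              dt = NULL, seed = NULL) {
  stopifnot(inherits(transient, "transient_model"),
            inherits(acv, "autocov_model"))
  if (is.null(dt)) dt <- acv$dt
  if (abs(dt - acv$dt) > 1e-12 * acv$dt) {
    stop("dt (", dt, ") does not match the autocovariance model's dt (",
         acv$dt, "); rediscretize the model instead")
  }
  n_points <- as.integer(n_points)
  n_series <- as.integer(n_series)
  stopifnot(n_points >= 2L, n_series >= 1L)

  gamma <- acv$gamma
  band <- min(length(gamma) - 1L, n_points - 1L)
  g0 <- gamma[1L]
  if (g0 <= 0) stop("autocovariance model has zero variance")

  build <- function(jitter) {
    diags <- lapply(0:band, function(k) rep(gamma[k + 1L], n_points - k))
    diags[[1L]] <- diags[[1L]] + jitter
    Matrix::bandSparse(n_points, k = 0:band, diagonals = diags,
                       symmetric = TRUE)
  }
  jitter <- 0
  lower <- NULL
  repeat {
    m <- build(jitter)
    lower <- tryCatch(
      suppressWarnings(Matrix::t(Matrix::chol(m, pivot = FALSE))),
      error = function(e) NULL
    )
    if (!is.null(lower)) break
    jitter <- if (jitter == 0) 1e-10 * g0 else jitter * 10
    if (jitter > 1e-4 * g0) {
      lam_min <- if (n_points <= 2048L) {
        min(eigen(as.matrix(build(0)), symmetric = TRUE,
                  only.values = TRUE)$values)
      } else {
        NA_real_
      }
      stop("autocovariance matrix is not positive definite even with ",
           "diagonal jitter up to 1e-4 * gamma_0 (smallest eigenvalue: ",
           lam_min, ")")
    }
  }

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_series)
  trans <- transient_values(transient, (0:(n_points - 1L)) * dt)
  values <- matrix(0, n_points, n_series)
  for (j in seq_len(n_series)) {
    set.seed(child_seeds[j])
    z <- stats::rnorm(n_points)
    values[, j] <- as.numeric(lower %*% z) + trans
  }

  structure(
    list(
      values = values, dt = dt, t0 = 0, true_mean = 0,
      transient = transient, acv = acv, seed = seed,
      variant = "standard", variant_params = list()
    ),
    class = "synthetic_ensemble"
  )
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ensemble> %d series x %d points, dt = %g ns, variant = %s\n",
    ncol(x$values), nrow(x$values), x$dt, x$variant
  ))
  invisible(x)
}

#' Number of series in an ensemble
#' @param ens A `synthetic_ensemble`.
#' @return Integer count.
#' @export
n_series <- function(ens) ncol(ens$values)

#' Extract one series from an ensemble
#' @param ens A `synthetic_ensemble`.
#' @param i Series index.
#' @return A [sim_series()].
#' @export
ensemble_series <- function(ens, i) {
  sim_series(ens$values[, i], dt = ens$dt, t0 = ens$t0)
}

#' Derive a dataset variant from an ensemble
#'
#' Reproduces the dataset variants used to probe heuristic robustness:
#'
#' * `"standard"`: the ensemble unchanged.
#' * `"short"`: keep only the first `duration` ns of every series.
#' * `"subsampled"`: keep every `k`-th point and multiply `dt` by `k`.
#' * `"noisy"`: regenerate from the same transient and root seed (hence the
#'   same noise streams) with every autocovariance term scaled by `factor`.
#' * `"block_averaged"`: replace nonoverlapping blocks of `block` points by
#'   their averages and multiply `dt` by `block`; a remainder that does not
#'   fill a block is dropped with a message.
#'
#' @param ens A `synthetic_ensemble`.
#' @param variant One of the variant names above.
#' @param duration Head duration in ns (for `"short"`).
#' @param k Subsampling interval in samples (for `"subsampled"`).
#' @param factor Autocovariance scale factor (for `"noisy"`), e.g.
#'   `sqrt(5)`.
#' @param block Block size in samples (for `"block_averaged"`).
#' @return A new `synthetic_ensemble` with variant provenance recorded.
#' @export
make_variant <- function(ens, variant = c("standard", "short", "subsampled",
                                          "noisy", "block_averaged"),
                         duration = NULL, k = NULL, factor = NULL,
                         block = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(ens, "synthetic_ensemble"))
  n <- nrow(ens$values)
  out <- ens

  check_len <- function(len) {
    if (len < 10L) {
      stop("variant would leave ", len, " points (< 10); refusing")
    }
  }

  if (variant == "standard") {
    return(ens)
  } else if (variant == "short") {
    if (is.null(duration) || duration <= 0) stop("short variant needs a positive duration")
    keep <- min(n, as.integer(round(duration / ens$dt)))
    check_len(keep)
    out$values <- ens$values[seq_len(keep), , drop = FALSE]
    out$variant_params <- list(duration = duration)
  } else if (variant == "subsampled") {
    if (is.null(k) || k < 1 || k != as.integer(k)) stop("subsampled variant needs a positive integer k")
    idx <- seq.int(1L, n, by = as.integer(k))
    check_len(length(idx))
    out$values <- ens$values[idx, , drop = FALSE]
    out$dt <- ens$dt * k
    out$variant_params <- list(k = as.integer(k))
  } else if (variant == "noisy") {
    if (is.null(factor) || factor <= 0) stop("noisy variant needs a positive factor")
    acv2 <- autocov_model(ens$acv$gamma * factor, ens$acv$dt)
    re <- generate_ensemble(ens$transient, acv2, n_series = ncol(ens$values),
                            n_points = n, seed = ens$seed)
    out <- re
    out$variant_params <- list(factor = factor)
  } else { # block_averaged
    if (is.null(block) || block < 1 || block != as.integer(block)) stop("block_averaged variant needs a positive integer block")
    block <- as.integer(block)
    nb <- n %/% block
    check_len(nb)
    if (n %% block != 0L) {
      message("dropping ", n %% block, " trailing points that do not fill a block")
    }
    x <- ens$values[seq_len(nb * block), , drop = FALSE]
    dim(x) <- c(block, nb, ncol(ens$values))
    out$values <- colMeans(x) # block means: nb x n_series
    out$dt <- ens$dt * block
    out$variant_params <- list(block = block)
  }
  out$variant <- variant
  out
}
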