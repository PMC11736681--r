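Package: truncsel
Title: Truncation-Point Selection for Autocorrelated Simulation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized marginal-standard-error-rule (MSER) heuristics for
    choosing the truncation ("equilibration") point of autocorrelated scalar
    time series from molecular simulations, such as free-energy estimates from
    absolute binding free energy calculations. Provides a family of
    variance-of-the-mean estimators (uncorrelated, triangular lag windows,
    Geyer initial-sequence rules, first-negative-autocovariance truncation,
    and a smoothed-lag convex variant), effective-sample-size computation,
    selection by minimum marginal standard error, left-most local minimum or
    maximum effective sample size, a generator of synthetic correlated
    Gaussian ensembles with known true means (Cholesky factorization of a
    banded autocovariance matrix plus a biexponential initial transient), and
    a benchmarking harness (RMSE/bias/SD decomposition with bootstrap
    confidence intervals, fixed-truncation reference curves, confidence
    interval coverage, and subsampling variance-inflation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
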