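# truncsel

Truncation-point selection ("equilibration detection") for autocorrelated
scalar time series from molecular simulations — free-energy estimates,
observable traces, or any other scalar sampled on a uniform time grid.

## The problem and the method

A simulation started from an unrepresentative configuration carries an
initial transient: averaging from the start biases the estimate, while
discarding too much inflates its variance. Writing `n0` for the first
retained sample and `⟨A⟩_[n0,N]` for the truncated mean, the ensemble
error decomposes as `RMSE² = Bias² + SD²`, and a good truncation point
balances the two.

`truncsel` implements a generalized **marginal standard error rule**:
scan candidate truncation points, estimate the variance of the truncated
mean at each, and keep the candidate minimizing the marginal standard
error `sqrt(Var̂(⟨A⟩_[n0,N]))`. The variance estimator is the knob. All
estimators sum the (deliberately uncorrected, divisor-`N`) truncated
autocovariances `γ̂_t` and differ in which lags enter and with what
weight:

| method | estimate of `N·Var̂` | character |
|---|---|---|
| `uncorrelated` | `γ̂₀` | classical rule; blind to correlation, truncates early |
| `window` (size `s`) | `γ̂₀ + 2Σ (1 − t/(s+1)) γ̂_t` | Bartlett taper ≡ overlapping batch means at `b = s+1` |
| `initial_*` | `−γ̂₀ + 2Σ Γ̂_m` | Geyer initial positive / monotone / convex sequence rules on `Γ̂_m = γ̂_2m + γ̂_2m+1` |
| `chodera` | `γ̂₀ + 2Σ_{t<T} γ̂_t` | stop at the first nonpositive `γ̂_T` |
| `smoothed_lag_convex` | convex rule, lag cap never increasing along the scan | removes single-candidate troughs |

Selection modes: global minimum of the marginal standard error
(`min_mse`, the default), left-most local minimum (`llm`), and maximum
effective sample size (`max_ess`, with `ESS = γ̂₀/Var̂`). The final 10% of
the series is excluded from the candidate grid by default. The `sqrt(N)`
window is the default method: across transient-dominated and
transient-free ensembles it stays within a few tens of percent of the
best method while avoiding the wide, sometimes bimodal discard-time
distributions of the initial-sequence estimators.

The package also ships the machinery to *test* such heuristics without
external data: a generator of synthetic ensembles with exactly known true
means (Cholesky-correlated Gaussian noise plus a biexponential transient,
with presets modeled on five absolute binding free energy systems and a
surrogate autocovariance calibrated to their recorded summary
descriptors), dataset variants (short / subsampled / noisy /
block-averaged), and a benchmarking harness (RMSE–bias–SD decomposition
with percentile-bootstrap intervals, fixed-truncation reference curves,
confidence-interval coverage, subsampling variance inflation).

## Worked example

```r
library(truncsel)

# a strong-transient synthetic ensemble from the MDM2-Pip2 preset,
# discretized at 2 ps, 8 ns per series
pip2 <- abfe_presets(dt = 0.002)[["MDM2-Pip2"]]
ens  <- generate_ensemble(pip2$transient, pip2$acv,
                          n_series = 50, n_points = 4000, seed = 1)

s <- ensemble_series(ens, 1)
select_truncation(s, estimator_spec("window", window_size = "sqrt"),
                  stride = 20)
#> <truncation_result> window / min_mse
#>   n0* = 3000 (t* = 6 ns), mean = 0.00547191, mse = 0.05705, ESS = 119
```

For this trajectory the rule discards the first 6 ns (the preset's slow
transient has amplitude 3.6 kcal/mol and half-life 0.8 ns, largely hidden
in noise with `γ̂₀ ≈ 0.5`), leaving a truncated mean of 0.005 kcal/mol —
the generator's true mean is 0 — with a marginal standard error of
0.057 kcal/mol and about 119 effectively independent samples.

Scoring the same heuristic over the whole ensemble against the known true
mean:

```r
ev <- evaluate_heuristic(ens, estimator_spec("window", window_size = "sqrt"),
                         stride = 20, n_boot = 1000, seed = 2)
ev$metrics
#> <ensemble_metrics> n = 50: rmse 0.1288 [0.1073, 0.1517], bias 0.08265, sd 0.09882
```

so on 50 trajectories the `sqrt(N)`-window rule leaves an ensemble RMSE of
0.129 kcal/mol (95% bootstrap CI in brackets), split between residual
transient bias (0.083) and trajectory-to-trajectory spread (0.099).

A command-line front end wraps the same functionality
(`exec/truncsel detect|synth|benchmark`; see `truncsel help`).

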