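#include <Rcpp.h>
using namespace Rcpp;

// Autocovariance with the uncorrected convention used throughout the package:
// gamma_t = (1/n) * sum_{i=1}^{n-t} (x_i - xbar) (x_{i+t} - xbar),
// i.e. divisor n at every lag (no n - t correction) and centering at the
// sample mean of the (already truncated) series.

static double lag_product(const std::vector<double> &xc, int t) {
    const int n = (int)xc.size();
    double s = 0.0;
    for (int i = 0; i + t < n; ++i) s += xc[i] * xc[i + t];
    return s / n;
}

static std::vector<double> centered(const NumericVector &x) {
    const int n = x.size();
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += x[i];
    m /= n;
    std::vector<double> xc(n);
    for (int i = 0; i < n; ++i) xc[i] = x[i] - m;
    return xc;
}

// [[Rcpp::export]]
NumericVector cpp_acv(NumericVector x, int lag_max) {
    std::vector<double> xc = centered(x);
    NumericVector g(lag_max + 1);
    for (int t = 0; t <= lag_max; ++t) g[t] = lag_product(xc, t);
    return g;
}

// Lags 0, 1, 2, ... until the first lag t >= 1 with gamma_t <= 0 (that lag is
// included in the result) or until lag_cap. Serves the first-negative
// truncation rule, which sums gamma up to (but excluding) that lag.
// [[Rcpp::export]]
NumericVector cpp_acv_first_nonpos(NumericVector x, int lag_cap) {
    std::vector<double> xc = centered(x);
    std::vector<double> g;
    g.push_back(lag_product(xc, 0));
    for (int t = 1; t <= lag_cap; ++t) {
        double v = lag_product(xc, t);
        g.push_back(v);
        if (v <= 0.0) break;
    }
    return wrap(g);
}

// Lags in pairs (2m, 2m + 1) until the first pair sum
// Gamma_m = gamma_{2m} + gamma_{2m+1} is nonpositive (pair included) or until
// pair index pair_cap (inclusive) or lags run out. Serves the Geyer
// initial-sequence estimators, which keep pairs strictly before the first
// nonpositive one.
// [[Rcpp::export]]
NumericVector cpp_acv_gamma_pairs(NumericVector x, int pair_cap) {
    std::vector<double> xc = centered(x);
    const int n = (int)xc.size();
    std::vector<double> g;
    for (int m = 0; m <= pair_cap; ++m) {
        int t0 = 2 * m, t1 = 2 * m + 1;
        if (t1 > n - 1) break;  // no complete pair left
        double a = lag_product(xc, t0);
        double b = lag_product(xc, t1);
        g.push_back(a);
        g.push_back(b);
        if (a + b <= 0.0) break;
    }
    return wrap(g);
}
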