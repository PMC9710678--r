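#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lagged autocorrelation descriptor of a translated sequence.
// S is n x p (residues x scales); output is length p * max_lag,
// scale-major (scale j block of max_lag lags).
// Conventions (documented in the package):
//   lag >= n          -> 0
//   sd(column) == 0   -> 0 for every lag of that scale
// Mean and s.d. are taken over the full column, population form (divisor n).
// [[Rcpp::export]]
NumericVector ac_features_cpp(const NumericMatrix& S, int max_lag) {
  const int n = S.nrow(), p = S.ncol();
  NumericVector out(p * max_lag);
  for (int j = 0; j < p; ++j) {
    // constant column (e.g. homopolymer): exactly zero by convention,
    // checked directly so accumulation rounding cannot fake a variance
    double lo = S(0, j), hi = S(0, j);
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, S(i, j));
      hi = std::max(hi, S(i, j));
    }
    if (lo == hi) continue;
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += S(i, j);
    mu /= n;
    double var = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = S(i, j) - mu;
      var += d * d;
    }
    var /= n;
    if (var <= 0.0) continue;  // zero-fill convention
    for (int lag = 1; lag <= max_lag; ++lag) {
      if (lag >= n) break;     // remaining lags stay 0
      double acc = 0.0;
      for (int i = 0; i < n - lag; ++i)
        acc += (S(i, j) - mu) * (S(i + lag, j) - mu);
      out[j * max_lag + (lag - 1)] = acc / ((n - lag) * var);
    }
  }
  return out;
}
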