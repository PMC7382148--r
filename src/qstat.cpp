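#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Joint cumulative probability that N independent U(0,1) variables have
// their i-th order statistic <= r_i for every i, for one sorted tuple.
// Recursion: V_0 = 1; V_k = sum_{i=1..k} (-1)^(i-1) r_{N-k+1}^i / i! * V_{k-i};
// q = N! * V_N.
static double q_from_sorted(const double* r, int n) {
  std::vector<double> V(n + 1);
  V[0] = 1.0;
  for (int k = 1; k <= n; ++k) {
    double rk = r[n - k]; // r_{N-k+1}, 1-based
    double term = 0.0;
    double pow_r = 1.0;   // rk^i
    double fact = 1.0;    // i!
    double sign = 1.0;
    for (int i = 1; i <= k; ++i) {
      pow_r *= rk;
      fact *= i;
      term += sign * pow_r / fact * V[k - i];
      sign = -sign;
    }
    V[k] = term;
  }
  double q = V[n];
  for (int i = 2; i <= n; ++i) q *= i;
  if (q < 0.0) q = 0.0;
  if (q > 1.0) q = 1.0;
  return q;
}

// Row-wise Q over a matrix of normalized ranks; NA cells mean the
// protein is absent from that list, so N reduces to the number of
// available values. Rows with no available value return NA.
// [[Rcpp::export]]
NumericVector q_stat_rows(NumericMatrix ranks) {
  int nr = ranks.nrow(), nc = ranks.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    int n = 0;
    for (int j = 0; j < nc; ++j) {
      double v = ranks(i, j);
      if (!NumericVector::is_na(v)) buf[n++] = v;
    }
    if (n == 0) { out[i] = NA_REAL; continue; }
    std::sort(buf.begin(), buf.begin() + n);
    out[i] = q_from_sorted(buf.data(), n);
  }
  return out;
}

// Row-wise MAD (scaled by 1.4826) of a residual matrix, ignoring cells
// where the mask is FALSE. Used by the IRLS robust-regression engine.
// [[Rcpp::export]]
NumericVector row_mad_masked(NumericMatrix E, LogicalMatrix M) {
  int nr = E.nrow(), nc = E.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc), dev(nc);
  for (int i = 0; i < nr; ++i) {
    int n = 0;
    for (int j = 0; j < nc; ++j) {
      if (M(i, j)) buf[n++] = E(i, j);
    }
    if (n == 0) { out[i] = NA_REAL; continue; }
    auto med_of = [&](std::vector<double>& v, int m) {
      std::nth_element(v.begin(), v.begin() + m / 2, v.begin() + m);
      double hi = v[m / 2];
      if (m % 2 == 1) return hi;
      std::nth_element(v.begin(), v.begin() + m / 2 - 1, v.begin() + m / 2);
      return 0.5 * (hi + v[m / 2 - 1]);
    };
    // center at zero (rlm convention): s = 1.4826 * median(|e|)
    for (int k = 0; k < n; ++k) dev[k] = std::fabs(buf[k]);
    out[i] = 1.4826 * med_of(dev, n);
  }
  return out;
}
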