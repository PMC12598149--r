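#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Nonnegative sparse AR(1) deconvolution by pool adjacent violators:
//   min 0.5 * ||y - c||^2 + lambda * sum(s),  s[t] = c[t] - gamma*c[t-1] >= 0,
// with c >= 0. The L1 term is absorbed into the data (its gradient w.r.t.
// c[t] is lambda*(1-gamma) for t<T and lambda at t=T), after which pools of
// frames sharing one free height are merged left whenever the nonnegativity
// constraint between adjacent pools is violated.
// [[Rcpp::export]]
List oasis_ar1(NumericVector y, double gamma, double lambda) {
  int n = y.size();
  NumericVector c(n), s(n);
  if (n == 0) return List::create(_["C"] = c, _["s"] = s);

  std::vector<double> v(n), w(n), g1(n);
  std::vector<int> t0(n), len(n);
  int k = -1;
  for (int i = 0; i < n; ++i) {
    double yt = y[i] - lambda * (i == n - 1 ? 1.0 : (1.0 - gamma));
    ++k;
    v[k] = yt; w[k] = 1.0; t0[k] = i; len[k] = 1; g1[k] = gamma; // gamma^len
    while (k > 0 && v[k] / w[k] < g1[k - 1] * (v[k - 1] / w[k - 1])) {
      // merge pool k into k-1
      double g = g1[k - 1];
      v[k - 1] += g * v[k];
      w[k - 1] += g * g * w[k];
      len[k - 1] += len[k];
      g1[k - 1] = g * g1[k];
      --k;
    }
  }
  for (int p = 0; p <= k; ++p) {
    double h = v[p] / w[p];
    if (h < 0.0) h = 0.0;
    double cur = h;
    for (int j = 0; j < len[p]; ++j) {
      c[t0[p] + j] = cur;
      cur *= gamma;
    }
  }
  s[0] = c[0];
  for (int i = 1; i < n; ++i) {
    double si = c[i] - gamma * c[i - 1];
    s[i] = si > 0.0 ? si : 0.0;
  }
  return List::create(_["C"] = c, _["s"] = s);
}
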