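#include <Rcpp.h>
using namespace Rcpp;

// phi_m(r) of the Pincus ApEn definition: mean over the N-m+1 template
// vectors of log(C_i), where C_i is the proportion of templates within
// Chebyshev distance r (self-matches included, so C_i > 0 always).
static double phi_m(const NumericVector& x, const int m, const double r) {
  const int n = x.size() - m + 1;
  std::vector<double> cnt(n, 1.0); // self-match
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) {
          d = a;
          if (d > r) break;
        }
      }
      if (d <= r) {
        cnt[i] += 1.0;
        cnt[j] += 1.0;
      }
    }
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log(cnt[i] / n);
  return s / n;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  return phi_m(x, m, r) - phi_m(x, m + 1, r);
}
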