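#include <Rcpp.h>
using namespace Rcpp;

// Square-rooted exponential-kernel density profile:
// G_j = sqrt( (1/N) sum_i exp(-k * |r_j - o_i|) )
// [[Rcpp::export]]
NumericVector cpp_sqrt_kde(NumericVector obs, NumericVector r, double k) {
  const int n = obs.size(), m = r.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    const double rj = r[j];
    for (int i = 0; i < n; ++i) {
      acc += std::exp(-k * std::fabs(rj - obs[i]));
    }
    out[j] = std::sqrt(acc / n);
  }
  return out;
}
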