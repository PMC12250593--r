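#include <Rcpp.h>
using namespace Rcpp;

// 1-D non-local means. For output sample i, candidate centers j run over a
// search window of length `search` around i; the squared patch distance is
// the mean squared difference over a patch of length `patch` (edges clamped),
// and weights are exp(-d2 / h^2), normalized to sum to one.
// [[Rcpp::export]]
NumericVector nlm_denoise_cpp(NumericVector x, int patch, int search, double h) {
  const int n = x.size();
  const int pr = patch / 2;   // patch radius
  const int sr = search / 2;  // search radius
  const double h2 = h * h;
  NumericVector out(n);

  for (int i = 0; i < n; ++i) {
    double wsum = 0.0, acc = 0.0;
    const int j0 = std::max(0, i - sr);
    const int j1 = std::min(n - 1, i + sr);
    for (int j = j0; j <= j1; ++j) {
      double d2 = 0.0;
      for (int k = -pr; k <= pr; ++k) {
        int ii = std::min(n - 1, std::max(0, i + k));
        int jj = std::min(n - 1, std::max(0, j + k));
        const double diff = x[ii] - x[jj];
        d2 += diff * diff;
      }
      d2 /= (2 * pr + 1);
      const double w = std::exp(-d2 / h2);
      wsum += w;
      acc += w * x[j];
    }
    out[i] = acc / wsum;
  }
  return out;
}
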