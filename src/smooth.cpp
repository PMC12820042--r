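#include <Rcpp.h>
using namespace Rcpp;

// Column-wise Gaussian smoothing of a T x K matrix with SD 'sigma' (in samples).
// The kernel is truncated at +-3 sigma and renormalised near the edges, so a
// constant series stays constant everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(NumericMatrix x, double sigma)
{
  const int T = x.nrow(), K = x.ncol();
  if (sigma <= 0) return clone(x);
  int h = (int)std::ceil(3.0 * sigma);
  if (h < 1) h = 1;
  std::vector<double> w(2 * h + 1);
  for (int k = -h; k <= h; ++k)
    w[k + h] = std::exp(-0.5 * (double)k * k / (sigma * sigma));

  NumericMatrix out(T, K);
  for (int j = 0; j < K; ++j) {
    const double* col = &x(0, j);
    for (int t = 0; t < T; ++t) {
      int lo = std::max(0, t - h), hi = std::min(T - 1, t + h);
      double s = 0.0, ws = 0.0;
      for (int u = lo; u <= hi; ++u) {
        double wk = w[u - t + h];
        s += wk * col[u];
        ws += wk;
      }
      out(t, j) = s / ws;
    }
  }
  return out;
}
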