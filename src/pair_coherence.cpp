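#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulated magnitude-squared wavelet coherence over a list of epoch
// pairs. coef holds complex Morlet coefficients with dims (T, C, F, E);
// smoothing is a truncated (+-3 sigma), edge-renormalised Gaussian over
// time with a per-frequency SD (in samples) plus a +-hw boxcar over
// frequency bins. Returns the per-element coherence sum and the count of
// valid pair contributions.

namespace {

struct Kernel {
  int h;
  std::vector<double> w;      // 2h+1 taps
  std::vector<double> norm;   // per-timepoint in-range weight sum
};

Kernel make_kernel(double sigma, int T)
{
  Kernel k;
  k.h = std::max(1, (int)std::ceil(3.0 * sigma));
  k.w.resize(2 * k.h + 1);
  for (int u = -k.h; u <= k.h; ++u)
    k.w[u + k.h] = std::exp(-0.5 * u * u / (sigma * sigma));
  k.norm.resize(T);
  double total = 0.0;
  for (double v : k.w) total += v;
  for (int t = 0; t < T; ++t) {
    int lo = std::max(0, t - k.h), hi = std::min(T - 1, t + k.h);
    if (hi - lo == 2 * k.h) {
      k.norm[t] = total;
    } else {
      double s = 0.0;
      for (int u = lo; u <= hi; ++u) s += k.w[u - t + k.h];
      k.norm[t] = s;
    }
  }
  return k;
}

// smooth a length-T series in place (re/im separately handled by caller)
void smooth_series(const double* x, double* out, int T, const Kernel& k)
{
  for (int t = 0; t < T; ++t) {
    int lo = std::max(0, t - k.h), hi = std::min(T - 1, t + k.h);
    double s = 0.0;
    for (int u = lo; u <= hi; ++u) s += k.w[u - t + k.h] * x[u];
    out[t] = s / k.norm[t];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_pair_coherence(ComplexVector coef, IntegerVector dims,
                        IntegerVector ii, IntegerVector jj,
                        NumericVector sigma, int hw)
{
  const int T = dims[0], C = dims[1], F = dims[2], E = dims[3];
  if ((R_xlen_t)T * C * F * E != coef.size()) stop("coef size mismatch");
  if (ii.size() != jj.size()) stop("pair index length mismatch");
  const int P = ii.size();
  const Rcomplex* W = COMPLEX(coef);
  auto at = [&](int t, int c, int f, int e) -> const Rcomplex& {
    return W[t + (R_xlen_t)T * (c + (R_xlen_t)C * (f + (R_xlen_t)F * e))];
  };

  std::vector<Kernel> ker;
  ker.reserve(F);
  for (int f = 0; f < F; ++f) ker.push_back(make_kernel(sigma[f], T));

  // smoothed auto-power per (t, c, f, e), then frequency boxcar
  std::vector<double> autos((size_t)T * C * F * E);
  std::vector<double> buf(T), sm(T);
  for (int e = 0; e < E; ++e)
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c) {
        for (int t = 0; t < T; ++t) {
          const Rcomplex& z = at(t, c, f, e);
          buf[t] = z.r * z.r + z.i * z.i;
        }
        smooth_series(buf.data(), sm.data(), T, ker[f]);
        double* dst = &autos[(size_t)T * (c + (size_t)C * (f + (size_t)F * e))];
        std::copy(sm.begin(), sm.end(), dst);
      }
  if (hw >= 1) {
    std::vector<double> tmp((size_t)T * C * F);
    for (int e = 0; e < E; ++e) {
      double* base = &autos[(size_t)T * C * F * e];
      std::copy(base, base + (size_t)T * C * F, tmp.begin());
      for (int f = 0; f < F; ++f) {
        int lo = std::max(0, f - hw), hi = std::min(F - 1, f + hw);
        for (int c = 0; c < C; ++c) {
          double* dst = base + (size_t)T * (c + (size_t)C * f);
          for (int t = 0; t < T; ++t) {
            double s = 0.0;
            for (int g = lo; g <= hi; ++g)
              s += tmp[t + (size_t)T * (c + (size_t)C * g)];
            dst[t] = s / (hi - lo + 1);
          }
        }
      }
    }
  }

  NumericVector acc(C * F * T), cnt(C * F * T);   // dims (C, F, T)
  std::vector<double> sre((size_t)T * C * F), sim_((size_t)T * C * F);
  std::vector<double> bre(T), bim(T);
  for (int p = 0; p < P; ++p) {
    const int e1 = ii[p] - 1, e2 = jj[p] - 1;
    if (e1 < 0 || e1 >= E || e2 < 0 || e2 >= E) stop("epoch index out of range");
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c) {
        for (int t = 0; t < T; ++t) {
          const Rcomplex& a = at(t, c, f, e1);
          const Rcomplex& b = at(t, c, f, e2);
          buf[t] = a.r * b.r + a.i * b.i;     // Re(a * conj(b))
          bim[t] = a.i * b.r - a.r * b.i;     // Im(a * conj(b))
        }
        smooth_series(buf.data(), bre.data(), T, ker[f]);
        std::copy(bre.begin(), bre.end(),
                  sre.begin() + (size_t)T * (c + (size_t)C * f));
        smooth_series(bim.data(), bre.data(), T, ker[f]);
        std::copy(bre.begin(), bre.end(),
                  sim_.begin() + (size_t)T * (c + (size_t)C * f));
      }
    for (int f = 0; f < F; ++f) {
      int lo = std::max(0, f - hw), hi = std::min(F - 1, f + hw);
      const int nb = hi - lo + 1;
      for (int c = 0; c < C; ++c) {
        const double* a1 = &autos[(size_t)T * (c + (size_t)C * (f + (size_t)F * e1))];
        const double* a2 = &autos[(size_t)T * (c + (size_t)C * (f + (size_t)F * e2))];
        for (int t = 0; t < T; ++t) {
          double re = 0.0, im = 0.0;
          for (int g = lo; g <= hi; ++g) {
            re += sre[t + (size_t)T * (c + (size_t)C * g)];
            im += sim_[t + (size_t)T * (c + (size_t)C * g)];
          }
          re /= nb; im /= nb;
          double den = a1[t] * a2[t];
          if (den <= 0) continue;
          double coh = (re * re + im * im) / den;
          if (coh < 0) coh = 0;
          if (coh > 1) coh = 1;
          const size_t k = c + (size_t)C * (f + (size_t)F * t);
          acc[k] += coh;
          cnt[k] += 1.0;
        }
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(C, F, T);
  cnt.attr("dim") = IntegerVector::create(C, F, T);
  return List::create(_["sum"] = acc, _["count"] = cnt);
}
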