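#include <Rcpp.h>
using namespace Rcpp;

// Fused decibel transform: out = 10 * log10(p / ref), with p laid out as
// (channel, freq, time) and ref as (channel, freq), recycled over time.
// [[Rcpp::export]]
NumericVector cpp_db(NumericVector p, NumericVector ref)
{
  const R_xlen_t n = p.size(), m = ref.size();
  NumericVector out(no_init(n));
  const double c = 10.0 / std::log(10.0);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = c * std::log(p[i] / ref[i % m]);
  out.attr("dim") = p.attr("dim");
  return out;
}
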