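#include <Rcpp.h>
using namespace Rcpp;

// Grid layout: element e = c + C*(f + F*t) over channels x frequencies x timepoints.
// Adjacency: +-1 frequency bin, +-1 timepoint, and montage channel neighbours at the
// same (f, t). Clusters never mix the sign of the t-statistic.

namespace {

struct Grid {
  int C, F, T;
  const std::vector<std::vector<int>>* nb;
};

// Flood fill from seed over same-sign supra-threshold elements.
// 'state' holds 0 = unvisited, otherwise cluster id.
double flood(const double* t, double tcrit, int sign, int seed, int id,
             std::vector<int>& state, std::vector<int>& stack, const Grid& g)
{
  double mass = 0.0;
  stack.clear();
  stack.push_back(seed);
  state[seed] = id;
  const int C = g.C, F = g.F;
  while (!stack.empty()) {
    int e = stack.back();
    stack.pop_back();
    mass += t[e];
    int c = e % C;
    int rem = e / C;
    int f = rem % F;
    int tt = rem / F;
    auto try_add = [&](int e2) {
      if (state[e2] == 0 && ((sign > 0 && t[e2] > tcrit) || (sign < 0 && t[e2] < -tcrit))) {
        state[e2] = id;
        stack.push_back(e2);
      }
    };
    if (f > 0)        try_add(e - C);
    if (f < F - 1)    try_add(e + C);
    if (tt > 0)       try_add(e - C * F);
    if (tt < g.T - 1) try_add(e + C * F);
    const std::vector<int>& nbc = (*g.nb)[c];
    for (size_t k = 0; k < nbc.size(); ++k)
      try_add(nbc[k] + C * (f + F * tt));
  }
  return mass;
}

std::vector<std::vector<int>> as_nb(const List& chan_nb)
{
  std::vector<std::vector<int>> nb(chan_nb.size());
  for (int c = 0; c < chan_nb.size(); ++c) {
    IntegerVector v = chan_nb[c];
    nb[c].assign(v.begin(), v.end());
  }
  return nb;
}

} // namespace

// [[Rcpp::export]]
List cpp_cluster_grid(NumericVector t, IntegerVector dims, List chan_nb, double tcrit)
{
  Grid g;
  g.C = dims[0]; g.F = dims[1]; g.T = dims[2];
  std::vector<std::vector<int>> nb = as_nb(chan_nb);
  g.nb = &nb;
  const int E = g.C * g.F * g.T;
  if (t.size() != E) stop("t-map length does not match dims");

  std::vector<int> state(E, 0), stack;
  std::vector<double> masses;
  std::vector<int> signs;
  int id = 0;
  const double* tp = REAL(t);
  for (int e = 0; e < E; ++e) {
    if (state[e] != 0) continue;
    int sign = 0;
    if (tp[e] > tcrit) sign = 1;
    else if (tp[e] < -tcrit) sign = -1;
    if (sign == 0) continue;
    ++id;
    masses.push_back(flood(tp, tcrit, sign, e, id, state, stack, g));
    signs.push_back(sign);
  }
  IntegerVector labels(E);
  for (int e = 0; e < E; ++e) labels[e] = state[e];
  return List::create(_["labels"] = labels,
                      _["mass"] = NumericVector(masses.begin(), masses.end()),
                      _["sign"] = IntegerVector(signs.begin(), signs.end()));
}

// Per permutation, the null statistic used for cluster p-values:
// tail 0 -> max |mass| over clusters of either sign (two-sided),
// tail 1 -> max positive mass, tail 2 -> max |negative mass|.
// Returns 0 for permutations with no supra-threshold cluster of the tail.
// [[Rcpp::export]]
NumericVector cpp_perm_max_mass(NumericMatrix tmat, IntegerVector dims, List chan_nb,
                                double tcrit, int tail)
{
  Grid g;
  g.C = dims[0]; g.F = dims[1]; g.T = dims[2];
  std::vector<std::vector<int>> nb = as_nb(chan_nb);
  g.nb = &nb;
  const int E = g.C * g.F * g.T;
  if (tmat.ncol() != E) stop("t-map length does not match dims");
  const int P = tmat.nrow();

  NumericVector out(P);
  std::vector<int> state(E), stack;
  std::vector<double> row(E);
  for (int p = 0; p < P; ++p) {
    for (int e = 0; e < E; ++e) row[e] = tmat(p, e);
    std::fill(state.begin(), state.end(), 0);
    int id = 0;
    double best = 0.0;
    for (int e = 0; e < E; ++e) {
      if (state[e] != 0) continue;
      int sign = 0;
      if (row[e] > tcrit) sign = 1;
      else if (row[e] < -tcrit) sign = -1;
      if (sign == 0) continue;
      if (tail == 1 && sign < 0) { // still mark, but do not score
        ++id;
        flood(row.data(), tcrit, sign, e, id, state, stack, g);
        continue;
      }
      if (tail == 2 && sign > 0) {
        ++id;
        flood(row.data(), tcrit, sign, e, id, state, stack, g);
        continue;
      }
      ++id;
      double m = flood(row.data(), tcrit, sign, e, id, state, stack, g);
      double score = (tail == 0) ? std::abs(m) : (tail == 1 ? m : -m);
      if (score > best) best = score;
    }
    out[p] = best;
  }
  return out;
}
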