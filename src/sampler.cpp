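#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site Gibbs sampler for a {0,1}-domain Ising model.
// One independent chain per observation: uniform random start, then
// `sweeps` full sequential passes where node i is redrawn from
// logistic(tau_i + sum_j omega_ij x_j). Local fields are maintained
// incrementally and the conditional probability of a node is recomputed
// only after a neighbor flips, so the steady-state cost per update is one
// uniform draw. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sample_ising_cpp(NumericVector tau, NumericMatrix omega,
                               int n_samples, int sweeps) {
  const int n = tau.size();
  // adjacency lists over nonzero couplings: estimated networks are sparse
  std::vector<std::vector<int> > nb(n);
  std::vector<std::vector<double> > wt(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double w = omega(i, j);
      if (j != i && w != 0.0) {
        nb[i].push_back(j);
        wt[i].push_back(w);
      }
    }
  }
  IntegerMatrix out(n_samples, n);
  std::vector<int> x(n);
  std::vector<double> eta(n), p(n);
  std::vector<char> stale(n);
  RNGScope scope;
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < n; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
    for (int i = 0; i < n; ++i) {
      double e = tau[i];
      for (size_t k = 0; k < nb[i].size(); ++k) e += wt[i][k] * x[nb[i][k]];
      eta[i] = e;
      stale[i] = 1;
    }
    for (int sweep = 0; sweep < sweeps; ++sweep) {
      for (int i = 0; i < n; ++i) {
        if (stale[i]) {
          p[i] = 1.0 / (1.0 + std::exp(-eta[i]));
          stale[i] = 0;
        }
        int xi = (unif_rand() < p[i]) ? 1 : 0;
        if (xi != x[i]) {
          double d = (xi > x[i]) ? 1.0 : -1.0;
          x[i] = xi;
          const std::vector<int>& nbi = nb[i];
          const std::vector<double>& wti = wt[i];
          for (size_t k = 0; k < nbi.size(); ++k) {
            eta[nbi[k]] += d * wti[k];
            stale[nbi[k]] = 1;
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) out(s, i) = x[i];
  }
  return out;
}
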