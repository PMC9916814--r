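#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Three-layer transfer operator with mirror boundaries:
// <f>(r) = lam_m(r) f(r-1) + lam_0(r) f(r) + lam_p(r) f(r+1),
// f(0) := f(1), f(M+1) := f(M).
static inline void local_avg(const std::vector<double>& f,
                             std::vector<double>& out,
                             const double* lm, const double* l0,
                             const double* lp, int M) {
  for (int r = 0; r < M; ++r) {
    double down = (r == 0) ? f[0] : f[r - 1];
    double up   = (r == M - 1) ? f[M - 1] : f[r + 1];
    out[r] = lm[r] * down + l0[r] * f[r] + lp[r] * up;
  }
}

// First-order Markov propagators for a branched chain on the 1D lattice.
//
// Nodes are in topological order (parent index < child index, root has
// parent 0).  'up' holds leaf-to-root subtree weights, 'comp' the
// complementary (rest-of-tree) weights; segment densities follow from the
// composition law rho_i = up_i * comp_i / G_i.  Every per-node vector is
// rescaled to unit maximum with the log of the scale tracked separately,
// so molecules of hundreds of segments in strong fields cannot under- or
// overflow.
//
// parent : 1-based parent ids (0 for root), topological order
// kind   : 1-based column of GW per node
// GW     : M x K matrix of segment weights exp(-u_X(r))
// lam_*  : step probabilities per layer
// L      : sites per layer
// Returns per-kind single-molecule site densities (M x K, normalised so
// that sum_r L * sum_kinds dens = N), log single-chain partition function,
// the max relative spread of q over evaluation nodes, and the per-node
// density matrix (M x n).
// [[Rcpp::export]]
List propagate_tree_cpp(IntegerVector parent, IntegerVector kind,
                        NumericMatrix GW,
                        NumericVector lam_m, NumericVector lam_0,
                        NumericVector lam_p, NumericVector L) {
  const int n = parent.size();
  const int M = GW.nrow();
  const int K = GW.ncol();
  if ((int)kind.size() != n) stop("kind/parent length mismatch");
  const double *lm = lam_m.begin(), *l0 = lam_0.begin(), *lp = lam_p.begin();

  // children lists
  std::vector<std::vector<int> > children(n);
  int root = -1;
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p == 0) {
      if (root >= 0) stop("multiple roots");
      root = i;
    } else {
      if (p < 1 || p > n || p - 1 >= i) stop("parents must precede children");
      children[p - 1].push_back(i);
    }
  }
  if (root != 0) stop("first node must be the root");

  std::vector<std::vector<double> > up(n), avgup(n), comp(n);
  std::vector<double> log_up(n, 0.0), log_comp(n, 0.0);
  std::vector<double> tmp(M);

  // leafward -> root pass
  for (int i = n - 1; i >= 0; --i) {
    up[i].resize(M);
    const int k = kind[i] - 1;
    if (k < 0 || k >= K) stop("kind index out of range");
    for (int r = 0; r < M; ++r) up[i][r] = GW(r, k);
    double ls = 0.0;
    for (size_t c = 0; c < children[i].size(); ++c) {
      int ch = children[i][c];
      for (int r = 0; r < M; ++r) up[i][r] *= avgup[ch][r];
      ls += log_up[ch];
    }
    double mx = 0.0;
    for (int r = 0; r < M; ++r) if (up[i][r] > mx) mx = up[i][r];
    if (!(mx > 0.0) || !std::isfinite(mx)) stop("non-finite propagator weight");
    for (int r = 0; r < M; ++r) up[i][r] /= mx;
    log_up[i] = ls + std::log(mx);
    avgup[i].resize(M);
    local_avg(up[i], avgup[i], lm, l0, lp, M);
  }

  // root -> leafward pass
  comp[root].resize(M);
  for (int r = 0; r < M; ++r) comp[root][r] = GW(r, kind[root] - 1);
  log_comp[root] = 0.0;
  for (int i = 0; i < n; ++i) {
    const int ki = kind[i] - 1;
    for (size_t c = 0; c < children[i].size(); ++c) {
      int ch = children[i][c];
      // weight at node i from everything except the branch towards ch
      for (int r = 0; r < M; ++r) {
        double denom = GW(r, ki) * avgup[ch][r];
        tmp[r] = comp[i][r] * up[i][r] / denom;
      }
      double lw = log_comp[i] + log_up[i] - log_up[ch];
      comp[ch].resize(M);
      local_avg(tmp, comp[ch], lm, l0, lp, M);
      const int kc = kind[ch] - 1;
      double mx = 0.0;
      for (int r = 0; r < M; ++r) {
        comp[ch][r] *= GW(r, kc);
        if (comp[ch][r] > mx) mx = comp[ch][r];
      }
      if (!(mx > 0.0) || !std::isfinite(mx)) stop("non-finite propagator weight");
      for (int r = 0; r < M; ++r) comp[ch][r] /= mx;
      log_comp[ch] = lw + std::log(mx);
    }
  }

  // densities, partition function, composition-law check
  NumericMatrix node_dens(M, n);
  NumericMatrix dens_kind(M, K);
  std::vector<double> logq_i(n);
  double logq = 0.0;
  for (int i = 0; i < n; ++i) {
    const int k = kind[i] - 1;
    double s = 0.0;
    for (int r = 0; r < M; ++r) {
      tmp[r] = up[i][r] * comp[i][r] / GW(r, k);
      s += L[r] * tmp[r];
    }
    logq_i[i] = std::log(s) + log_up[i] + log_comp[i];
    if (i == root) logq = logq_i[i];
    // store scaled; normalised below once logq is known (root first in order)
    for (int r = 0; r < M; ++r) node_dens(r, i) = tmp[r];
  }
  double qdev = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(std::expm1(logq_i[i] - logq));
    if (d > qdev) qdev = d;
    const int k = kind[i] - 1;
    double sc = std::exp(log_up[i] + log_comp[i] - logq);
    for (int r = 0; r < M; ++r) {
      double v = node_dens(r, i) * sc;
      node_dens(r, i) = v;
      dens_kind(r, k) += v;
    }
  }

  return List::create(_["dens_kind"] = dens_kind,
                      _["node_dens"] = node_dens,
                      _["logq"] = logq,
                      _["qdev"] = qdev);
}
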