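#include <Rcpp.h>
using namespace Rcpp;

// Relaxed-Brownian-motion log-likelihood by Felsenstein pruning.
//
// Branch variances are sigma2 * rel_rate * length + jump_var * n_jumps,
// where rel_rate is governed by the nearest ancestral shift (nested-clade
// convention: a shift rescales its branch and all descendants until
// overridden deeper).  Tips carry an additional measurement-error variance;
// the root state z0 is a model parameter.
//
// parent/child: 1-based node ids per edge row; preorder/postorder: 1-based
// edge row orders (parents first / children first).
// [[Rcpp::export]]
double rbm_loglik_cpp(IntegerVector parent, IntegerVector child,
                      NumericVector len, IntegerVector preorder,
                      IntegerVector postorder, int n_tip, int root,
                      NumericVector y, NumericVector shift_scalar,
                      IntegerVector jumps, double sigma2, double jump_var,
                      double me, double z0) {
  const int n_edge = parent.size();
  const int n_node = n_tip + n_edge;  // upper bound on node ids
  std::vector<int> parent_edge(n_node + 1, -1);
  for (int e = 0; e < n_edge; e++) parent_edge[child[e]] = e;

  // propagate relative rates root-to-tips
  std::vector<double> rate(n_edge);
  for (int i = 0; i < n_edge; i++) {
    int e = preorder[i] - 1;
    if (shift_scalar[e] > 0) {
      rate[e] = shift_scalar[e];
    } else {
      int pe = parent_edge[parent[e]];
      rate[e] = (pe >= 0) ? rate[pe] : 1.0;
    }
  }

  // pruning: per-node conditional mean and variance
  std::vector<double> mu(n_node + 1, 0.0), vv(n_node + 1, 0.0);
  std::vector<bool> seen(n_node + 1, false);
  for (int i = 1; i <= n_tip; i++) {
    mu[i] = y[i - 1];
    vv[i] = me;
    seen[i] = true;
  }
  double ll = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  for (int i = 0; i < n_edge; i++) {
    int e = postorder[i] - 1;
    int p = parent[e], c = child[e];
    double vc = vv[c] + sigma2 * rate[e] * len[e] + jump_var * jumps[e];
    if (!seen[p]) {
      mu[p] = mu[c];
      vv[p] = vc;
      seen[p] = true;
    } else {
      double vt = vv[p] + vc;
      if (vt <= 0) return R_NegInf;
      double d = mu[p] - mu[c];
      ll += -0.5 * (log2pi + std::log(vt) + d * d / vt);
      mu[p] = (mu[p] * vc + mu[c] * vv[p]) / vt;
      vv[p] = vv[p] * vc / vt;
    }
  }
  if (vv[root] <= 0) {
    if (std::abs(z0 - mu[root]) > 1e-12) return R_NegInf;
  } else {
    double d = z0 - mu[root];
    ll += -0.5 * (log2pi + std::log(vv[root]) + d * d / vv[root]);
  }
  if (!std::isfinite(ll)) return R_NegInf;
  return ll;
}

// Relative branch rates implied by a shift configuration (for summaries).
// [[Rcpp::export]]
NumericVector rbm_rel_rates_cpp(IntegerVector parent, IntegerVector child,
                                IntegerVector preorder,
                                NumericVector shift_scalar) {
  const int n_edge = parent.size();
  int max_node = 0;
  for (int e = 0; e < n_edge; e++) {
    if (parent[e] > max_node) max_node = parent[e];
    if (child[e] > max_node) max_node = child[e];
  }
  std::vector<int> parent_edge(max_node + 1, -1);
  for (int e = 0; e < n_edge; e++) parent_edge[child[e]] = e;
  NumericVector rate(n_edge);
  for (int i = 0; i < n_edge; i++) {
    int e = preorder[i] - 1;
    if (shift_scalar[e] > 0) {
      rate[e] = shift_scalar[e];
    } else {
      int pe = parent_edge[parent[e]];
      rate[e] = (pe >= 0) ? rate[pe] : 1.0;
    }
  }
  return rate;
}

// Mk pruning likelihood given an eigendecomposition Q = U diag(lam) Uinv.
// tip_state: 1-based state index per tip.  Returns the log-likelihood.
// [[Rcpp::export]]
double mk_loglik_cpp(IntegerVector parent, IntegerVector child,
                     NumericVector len, IntegerVector postorder, int n_tip,
                     int root, IntegerVector tip_state, NumericMatrix U,
                     NumericMatrix Uinv, NumericVector lam,
                     NumericVector root_prior) {
  const int n_edge = parent.size();
  const int s = lam.size();
  const int n_node = n_tip + n_edge;
  std::vector<double> L(s * (n_node + 1), 1.0);
  for (int i = 1; i <= n_tip; i++) {
    for (int j = 0; j < s; j++) L[i * s + j] = 0.0;
    L[i * s + (tip_state[i - 1] - 1)] = 1.0;
  }
  double logscale = 0.0;
  std::vector<double> P(s * s), tmp(s), msg(s);
  for (int i = 0; i < n_edge; i++) {
    int e = postorder[i] - 1;
    int p = parent[e], c = child[e];
    double t = len[e];
    // P = U diag(exp(lam t)) Uinv
    for (int a = 0; a < s; a++) tmp[a] = std::exp(lam[a] * t);
    for (int r = 0; r < s; r++)
      for (int q = 0; q < s; q++) {
        double acc = 0.0;
        for (int a = 0; a < s; a++)
          acc += U(r, a) * tmp[a] * Uinv(a, q);
        P[r * s + q] = acc;
      }
    double m = 0.0;
    for (int r = 0; r < s; r++) {
      double acc = 0.0;
      for (int q = 0; q < s; q++) acc += P[r * s + q] * L[c * s + q];
      msg[r] = acc;
    }
    for (int r = 0; r < s; r++) {
      L[p * s + r] *= msg[r];
      if (L[p * s + r] > m) m = L[p * s + r];
    }
    if (m > 0 && m < 1e-100) {
      for (int r = 0; r < s; r++) L[p * s + r] /= m;
      logscale += std::log(m);
    }
  }
  double val = 0.0;
  for (int r = 0; r < s; r++) val += root_prior[r] * L[root * s + r];
  if (val <= 0 || !std::isfinite(val)) return R_NegInf;
  return std::log(val) + logscale;
}
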