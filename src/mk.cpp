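#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Log-likelihood of a binary character matrix on a tree under the two-state
// Mk model with free state frequencies and a discrete rate mixture
// (FreeRate). Felsenstein pruning over compressed site patterns with
// per-node per-site scaling. Branch lengths are expected state changes per
// character at relative rate 1: P_ij(t) = pi_j + (delta_ij - pi_j)
// * exp(-beta * r * t), beta = 1 / (2 * pi0 * pi1).
//
// edge: E x 2 matrix of 1-based node ids in postorder (parent, child);
// tips are 1..n_tip, the root is the parent never appearing as a child.
// states: n_tip x S matrix of 0/1 tip states, row i = tip id i.
// patw: S pattern multiplicities. rates/weights: mixture categories.
// [[Rcpp::export(name = ".mk_loglik_cpp")]]
double mk_loglik_cpp(const IntegerMatrix& edge, int n_tip,
                     const NumericVector& brlen, const IntegerMatrix& states,
                     const NumericVector& patw, double pi0,
                     const NumericVector& rates,
                     const NumericVector& weights);

// Golden-section maximization of the log-likelihood over one branch
// length, with an optional bracketing pass over a fixed grid (the
// per-branch profile can be bimodal on noisy binary data).
static void opt_edge_golden(const IntegerMatrix& edge, int n_tip,
                            NumericVector& brlen,
                            const IntegerMatrix& states,
                            const NumericVector& patw, double pi0,
                            const NumericVector& rates,
                            const NumericVector& weights, int e,
                            double bl_min, double bl_max, double tol,
                            bool bracket, double& best_x,
                            double& best_ll) {
  const double save = brlen[e];
  double lo = bl_min, hi = bl_max;
  best_x = save;
  best_ll = -1e308;
  auto f = [&](double x) {
    brlen[e] = x;
    return mk_loglik_cpp(edge, n_tip, brlen, states, patw, pi0, rates,
                         weights);
  };
  if (bracket) {
    const double grid[] = {bl_min, 0.01, 0.05, 0.1,  0.25, 0.5,
                           1.0,    2.5,  5.0,  bl_max};
    const int G = 10;
    double vals[12];
    int ibest = 0;
    for (int i = 0; i < G; ++i) {
      vals[i] = f(grid[i]);
      if (vals[i] > vals[ibest]) ibest = i;
    }
    best_x = grid[ibest];
    best_ll = vals[ibest];
    lo = grid[ibest > 0 ? ibest - 1 : 0];
    hi = grid[ibest < G - 1 ? ibest + 1 : G - 1];
  }
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 >= f2) {
      b = x2;
      x2 = x1;
      f2 = f1;
      x1 = b - gr * (b - a);
      f1 = f(x1);
    } else {
      a = x1;
      x1 = x2;
      f1 = f2;
      x2 = a + gr * (b - a);
      f2 = f(x2);
    }
  }
  const double xm = (a + b) / 2.0;
  const double fm = f(xm);
  if (fm > best_ll) {
    best_ll = fm;
    best_x = xm;
  }
  if (f1 > best_ll) {
    best_ll = f1;
    best_x = x1;
  }
  if (f2 > best_ll) {
    best_ll = f2;
    best_x = x2;
  }
  brlen[e] = save;
}

// Coordinate-ascent optimization of all branch lengths (sweeps until the
// per-sweep gain drops below eps); returns the optimized lengths and the
// final log-likelihood.
// [[Rcpp::export(name = ".mk_opt_branches_cpp")]]
List mk_opt_branches_cpp(const IntegerMatrix& edge, int n_tip,
                         const NumericVector& brlen0,
                         const IntegerMatrix& states,
                         const NumericVector& patw, double pi0,
                         const NumericVector& rates,
                         const NumericVector& weights, double bl_min,
                         double bl_max, double tol, double eps,
                         int max_cycles) {
  NumericVector brlen = clone(brlen0);
  for (int e = 0; e < brlen.size(); ++e) {
    if (brlen[e] < bl_min) brlen[e] = bl_min;
    if (brlen[e] > bl_max) brlen[e] = bl_max;
  }
  double ll = mk_loglik_cpp(edge, n_tip, brlen, states, patw, pi0, rates,
                            weights);
  for (int cycle = 0; cycle < max_cycles; ++cycle) {
    const double ll_before = ll;
    for (int e = 0; e < brlen.size(); ++e) {
      double x, v;
      opt_edge_golden(edge, n_tip, brlen, states, patw, pi0, rates,
                      weights, e, bl_min, bl_max, tol, cycle == 0, x, v);
      if (v > ll) {
        brlen[e] = x;
        ll = v;
      }
    }
    if (ll - ll_before < eps) break;
  }
  return List::create(_["brlen"] = brlen, _["loglik"] = ll);
}

// Optimization of a single branch length (used to screen rearrangement
// candidates); returns the achieved log-likelihood.
// [[Rcpp::export(name = ".mk_opt_edge_cpp")]]
double mk_opt_edge_cpp(const IntegerMatrix& edge, int n_tip,
                       const NumericVector& brlen0,
                       const IntegerMatrix& states,
                       const NumericVector& patw, double pi0,
                       const NumericVector& rates,
                       const NumericVector& weights, int e_idx,
                       double bl_min, double bl_max, double tol) {
  NumericVector brlen = clone(brlen0);
  for (int e = 0; e < brlen.size(); ++e) {
    if (brlen[e] < bl_min) brlen[e] = bl_min;
    if (brlen[e] > bl_max) brlen[e] = bl_max;
  }
  double x, v;
  opt_edge_golden(edge, n_tip, brlen, states, patw, pi0, rates, weights,
                  e_idx - 1, bl_min, bl_max, tol, true, x, v);
  const double cur = mk_loglik_cpp(edge, n_tip, brlen, states, patw, pi0,
                                   rates, weights);
  return v > cur ? v : cur;
}

double mk_loglik_cpp(const IntegerMatrix& edge, int n_tip,
                     const NumericVector& brlen, const IntegerMatrix& states,
                     const NumericVector& patw, double pi0,
                     const NumericVector& rates,
                     const NumericVector& weights) {
  const int E = edge.nrow();
  const int S = states.ncol();
  const int n_node = n_tip + (E / 2) + 1;  // upper bound on node count
  int max_id = 0;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 0) > max_id) max_id = edge(e, 0);
    if (edge(e, 1) > max_id) max_id = edge(e, 1);
  }
  const int N = std::max(n_node, max_id);
  const double pi1 = 1.0 - pi0;
  const double beta = 1.0 / (2.0 * pi0 * pi1);
  const int K = rates.size();
  const int root = edge(E - 1, 0);

  // log site likelihood per category, then mix
  std::vector<double> logsl(static_cast<size_t>(K) * S);
  std::vector<double> L(static_cast<size_t>(N) * 2 * S);
  std::vector<double> logscale(S);

  for (int k = 0; k < K; ++k) {
    std::fill(L.begin(), L.end(), 1.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    for (int i = 0; i < n_tip; ++i) {
      double* Li = &L[static_cast<size_t>(i) * 2 * S];
      for (int s = 0; s < S; ++s) {
        if (states(i, s) == 0) {
          Li[2 * s + 1] = 0.0;
        } else {
          Li[2 * s] = 0.0;
        }
      }
    }
    for (int e = 0; e < E; ++e) {
      const int p = edge(e, 0) - 1;
      const int ch = edge(e, 1) - 1;
      const double ex = std::exp(-beta * rates[k] * brlen[e]);
      const double p00 = pi0 + pi1 * ex, p01 = pi1 - pi1 * ex;
      const double p10 = pi0 - pi0 * ex, p11 = pi1 + pi0 * ex;
      const double* Lc = &L[static_cast<size_t>(ch) * 2 * S];
      double* Lp = &L[static_cast<size_t>(p) * 2 * S];
      for (int s = 0; s < S; ++s) {
        const double c0 = Lc[2 * s], c1 = Lc[2 * s + 1];
        double v0 = Lp[2 * s] * (p00 * c0 + p01 * c1);
        double v1 = Lp[2 * s + 1] * (p10 * c0 + p11 * c1);
        // rescale the partial conditional when it drifts towards underflow;
        // the correction accumulates per site and applies at the root
        if (v0 < 1e-100 && v1 < 1e-100 && (v0 > 0.0 || v1 > 0.0)) {
          v0 *= 1e100;
          v1 *= 1e100;
          logscale[s] -= 230.25850929940458;  // log(1e100)
        }
        Lp[2 * s] = v0;
        Lp[2 * s + 1] = v1;
      }
    }
    const double* Lr = &L[static_cast<size_t>(root - 1) * 2 * S];
    for (int s = 0; s < S; ++s) {
      const double sl = pi0 * Lr[2 * s] + pi1 * Lr[2 * s + 1];
      logsl[static_cast<size_t>(k) * S + s] =
          (sl > 0.0) ? std::log(sl) + logscale[s] : -1e308;
    }
  }

  double total = 0.0;
  for (int s = 0; s < S; ++s) {
    double mx = -1e308;
    for (int k = 0; k < K; ++k) {
      const double v = logsl[static_cast<size_t>(k) * S + s];
      if (v > mx) mx = v;
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      acc += weights[k] *
             std::exp(logsl[static_cast<size_t>(k) * S + s] - mx);
    }
    total += patw[s] * (mx + std::log(acc));
  }
  return total;
}
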