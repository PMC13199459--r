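// Dual coordinate descent for the linear Crammer-Singer multi-class SVM.
//
// Dual problem (k classes, bias folded into the feature vector upstream):
//   min_alpha  1/2 sum_m ||w_m||^2 + sum_{i,m} e_i^m alpha_i^m
//   s.t.       sum_m alpha_i^m = 0,  alpha_i^m <= U_i^m
// with w_m = sum_i alpha_i^m x_i, e_i^m = 1 - [y_i == m],
// U_i^m = C [y_i == m].  Each per-observation subproblem is solved exactly
// (projection onto the simplex-like feasible set via a monotone
// root-find), so the dual objective is non-increasing by construction.
// Stopping: maximum per-observation KKT violation <= tol.

#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List mcsvm_cd_cpp(const NumericMatrix& X, const IntegerVector& y, int k,
                  double C, int max_epochs, double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix W(k, p);           // class weight vectors (rows)
  NumericMatrix alpha(n, k);
  std::vector<double> xsq(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    xsq[i] = s;
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> G(k), U(k), qv(k), beta(k);
  std::vector<double> trace;
  trace.reserve(max_epochs);
  bool converged = false;
  double max_viol = R_PosInf;
  int epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    max_viol = 0.0;

    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      const double A = xsq[i];
      if (A <= 0.0) continue;
      const int yi = y[i] - 1;

      for (int m = 0; m < k; ++m) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += W(m, j) * X(i, j);
        G[m] = s + (m == yi ? 0.0 : 1.0);
        U[m] = (m == yi ? C : 0.0);
      }

      // KKT violation before the update: coordinates strictly below their
      // bound must share the minimal gradient value.
      double gmin = G[0], gfree_max = -R_PosInf;
      for (int m = 0; m < k; ++m) {
        if (G[m] < gmin) gmin = G[m];
        if (alpha(i, m) < U[m] - 1e-12 && G[m] > gfree_max) gfree_max = G[m];
      }
      if (gfree_max > -R_PosInf) {
        const double viol = gfree_max - gmin;
        if (viol > max_viol) max_viol = viol;
      }

      // Exact subproblem: minimize (A/2)||b - q||^2 s.t. sum b = 0,
      // b_m <= U_m, where q_m = alpha_im - G_m / A.  Solution
      // b_m = min(U_m, q_m + nu) with nu the root of the monotone
      // sum-constraint; bracket then bisect.
      for (int m = 0; m < k; ++m) qv[m] = alpha(i, m) - G[m] / A;
      double lo = -1.0, hi = 1.0;
      auto gsum = [&](double nu) {
        double s = 0.0;
        for (int m = 0; m < k; ++m) s += std::min(U[m], qv[m] + nu);
        return s;
      };
      while (gsum(lo) > 0.0) lo *= 2.0;
      while (gsum(hi) < 0.0) hi *= 2.0;
      for (int it = 0; it < 100; ++it) {
        const double mid = 0.5 * (lo + hi);
        if (gsum(mid) < 0.0) lo = mid; else hi = mid;
      }
      const double nu = 0.5 * (lo + hi);
      for (int m = 0; m < k; ++m) beta[m] = std::min(U[m], qv[m] + nu);

      for (int m = 0; m < k; ++m) {
        const double delta = beta[m] - alpha(i, m);
        if (delta != 0.0) {
          for (int j = 0; j < p; ++j) W(m, j) += delta * X(i, j);
          alpha(i, m) = beta[m];
        }
      }
    }

    // dual objective for the trace
    double obj = 0.0;
    for (int m = 0; m < k; ++m)
      for (int j = 0; j < p; ++j) obj += 0.5 * W(m, j) * W(m, j);
    for (int i = 0; i < n; ++i)
      for (int m = 0; m < k; ++m)
        if (m != y[i] - 1) obj += alpha(i, m);
    trace.push_back(obj);
    epochs_run = epoch + 1;

    if (max_viol <= tol) { converged = true; break; }
  }

  return List::create(
    Named("W") = W,
    Named("alpha") = alpha,
    Named("dual_objective_trace") = NumericVector(trace.begin(), trace.end()),
    Named("epochs") = epochs_run,
    Named("converged") = converged,
    Named("max_violation") = max_viol
  );
}
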