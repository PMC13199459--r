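// Simulated log-likelihood of the random-parameters ordered logit with
// heterogeneity in the mean of a single random coefficient.
//
// Per observation i and draw r:
//   beta'_ir = a0 + z_i' a + sigma * eps_ir
//   v_ir     = x_i' beta + d_i * beta'_ir
//   p_ir     = F(tau_y - v) - F(tau_{y-1} - v)  (tau_0 = -inf, tau_3 = +inf)
//   P_i      = mean_r p_ir, floored at 1e-300 before the log.
//
// The gradient is analytic; per-observation scores are returned on request
// for BHHH covariance estimation.  Parameter order in the gradient:
//   beta (pf), a0, a (q), log_sd, tau1, tau2.

#include <Rcpp.h>
using namespace Rcpp;

static inline double cdf_logistic(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}
static inline double pdf_logistic(double x) {
  double e = std::exp(-std::fabs(x));
  double d = 1.0 + e;
  return e / (d * d);
}
static inline double cdf_gumbel(double x) {
  return std::exp(-std::exp(-x));
}
static inline double pdf_gumbel(double x) {
  return std::exp(-x - std::exp(-x));
}

// [[Rcpp::export]]
List rpol_sll_cpp(const NumericMatrix& Xf, const NumericVector& d,
                  const NumericMatrix& Z, const IntegerVector& y,
                  const NumericVector& beta, const NumericVector& a,
                  double log_sd, double tau1, double tau2,
                  const NumericMatrix& eps, bool gumbel,
                  bool want_grad, bool want_scores) {
  const int n = Xf.nrow(), pf = Xf.ncol(), q = Z.ncol(), R = eps.ncol();
  const int K = pf + 1 + q + 1 + 2;  // beta, a0, a, log_sd, tau1, tau2
  const double sigma = std::exp(log_sd);
  const double floor_p = 1e-300;

  double ll = 0.0;
  NumericVector grad(want_grad ? K : 0);
  NumericMatrix scores(want_scores ? n : 0, want_scores ? K : 0);

  double (*F)(double) = gumbel ? cdf_gumbel : cdf_logistic;
  double (*f)(double) = gumbel ? pdf_gumbel : pdf_logistic;

  for (int i = 0; i < n; ++i) {
    double vf = 0.0;
    for (int k = 0; k < pf; ++k) vf += Xf(i, k) * beta[k];
    double mu = a[0];
    for (int k = 0; k < q; ++k) mu += Z(i, k) * a[k + 1];
    const double di = d[i];
    const int yi = y[i];

    double P = 0.0, s_v = 0.0, s_veps = 0.0, s_t1 = 0.0, s_t2 = 0.0;
    for (int r = 0; r < R; ++r) {
      const double e = eps(i, r);
      const double v = vf + di * (mu + sigma * e);
      double p, dp_dv = 0.0, dp_dt1 = 0.0, dp_dt2 = 0.0;
      if (yi == 1) {
        const double u1 = tau1 - v;
        p = F(u1);
        if (want_grad || want_scores) {
          const double f1 = f(u1);
          dp_dv = -f1; dp_dt1 = f1;
        }
      } else if (yi == 2) {
        const double u1 = tau1 - v, u2 = tau2 - v;
        p = F(u2) - F(u1);
        if (want_grad || want_scores) {
          const double f1 = f(u1), f2 = f(u2);
          dp_dv = f1 - f2; dp_dt1 = -f1; dp_dt2 = f2;
        }
      } else {
        const double u2 = tau2 - v;
        p = 1.0 - F(u2);
        if (want_grad || want_scores) {
          const double f2 = f(u2);
          dp_dv = f2; dp_dt2 = -f2;
        }
      }
      P += p;
      if (want_grad || want_scores) {
        s_v += dp_dv;
        s_veps += dp_dv * e;
        s_t1 += dp_dt1;
        s_t2 += dp_dt2;
      }
    }
    P /= R;
    if (P < floor_p) P = floor_p;
    ll += std::log(P);

    if (want_grad || want_scores) {
      const double w = 1.0 / (P * R);
      // d v / d theta is draw-independent except through eps (log_sd term)
      for (int k = 0; k < pf; ++k) {
        const double g = w * s_v * Xf(i, k);
        if (want_grad) grad[k] += g;
        if (want_scores) scores(i, k) = g;
      }
      {
        const double g = w * s_v * di;
        if (want_grad) grad[pf] += g;
        if (want_scores) scores(i, pf) = g;
      }
      for (int k = 0; k < q; ++k) {
        const double g = w * s_v * di * Z(i, k);
        if (want_grad) grad[pf + 1 + k] += g;
        if (want_scores) scores(i, pf + 1 + k) = g;
      }
      {
        const double g = w * s_veps * di * sigma;
        if (want_grad) grad[pf + 1 + q] += g;
        if (want_scores) scores(i, pf + 1 + q) = g;
      }
      {
        const double g1 = w * s_t1, g2 = w * s_t2;
        if (want_grad) { grad[pf + 2 + q] += g1; grad[pf + 3 + q] += g2; }
        if (want_scores) { scores(i, pf + 2 + q) = g1; scores(i, pf + 3 + q) = g2; }
      }
    }
  }

  List out = List::create(Named("ll") = ll);
  if (want_grad) out["grad"] = grad;
  if (want_scores) out["scores"] = scores;
  return out;
}

// Simulation-averaged class probabilities, one row per observation.
// [[Rcpp::export]]
NumericMatrix rpol_probs_cpp(const NumericMatrix& Xf, const NumericVector& d,
                             const NumericMatrix& Z,
                             const NumericVector& beta, const NumericVector& a,
                             double log_sd, double tau1, double tau2,
                             const NumericMatrix& eps, bool gumbel) {
  const int n = Xf.nrow(), pf = Xf.ncol(), q = Z.ncol(), R = eps.ncol();
  const double sigma = std::exp(log_sd);
  NumericMatrix probs(n, 3);
  double (*F)(double) = gumbel ? cdf_gumbel : cdf_logistic;

  for (int i = 0; i < n; ++i) {
    double vf = 0.0;
    for (int k = 0; k < pf; ++k) vf += Xf(i, k) * beta[k];
    double mu = a[0];
    for (int k = 0; k < q; ++k) mu += Z(i, k) * a[k + 1];
    const double di = d[i];
    double p1 = 0.0, p2 = 0.0, p3 = 0.0;
    for (int r = 0; r < R; ++r) {
      const double v = vf + di * (mu + sigma * eps(i, r));
      const double F1 = F(tau1 - v), F2 = F(tau2 - v);
      p1 += F1;
      p2 += F2 - F1;
      p3 += 1.0 - F2;
    }
    probs(i, 0) = p1 / R;
    probs(i, 1) = p2 / R;
    probs(i, 2) = p3 / R;
  }
  return probs;
}
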