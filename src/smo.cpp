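#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimization for the dual of the 1-norm soft-margin SVM
// with a precomputed kernel and per-point box constraints:
//
//   min_a  0.5 a' Q a - e' a   s.t.  y' a = 0,  0 <= a_t <= C_t,
//
// where Q_ij = y_i y_j K_ij. Working pairs are chosen by maximal-violating-
// pair / second-order selection; convergence when the maximal KKT violation
// m(a) - M(a) drops below eps.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double eps, int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel must be square");
  if (y.size() != n || C.size() != n) stop("length mismatch");
  const double TAU = 1e-12;

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    // i = argmax over I_up of -y_t G_t
    int i = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      if (in_up) {
        double v = -y[t] * G[t];
        if (v > Gmax) { Gmax = v; i = t; }
      }
    }
    if (i < 0) { converged = true; break; }

    // j = second-order choice within I_low among violating candidates
    int j = -1;
    double Gmin = std::numeric_limits<double>::infinity();
    double obj_best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C[t]);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < Gmin) Gmin = v;
      double b = Gmax - v;
      if (b > 0) {
        // curvature along the feasible pair direction; label-independent
        double quad = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (quad <= 0) quad = TAU;
        double dec = -(b * b) / quad;
        if (dec < obj_best) { obj_best = dec; j = t; }
      }
    }
    if (j < 0 || Gmax - Gmin < eps) { converged = (Gmax - Gmin < eps); break; }

    // analytic two-variable update: a_i += t, a_j -= s*t, s = y_i y_j
    double s = y[i] * y[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    double tstar = -(G[i] - s * G[j]) / quad;

    double t_lo = -alpha[i];
    double t_hi = C[i] - alpha[i];
    if (s > 0) {  // a_j_new = a_j - t in [0, C_j]
      if (alpha[j] - C[j] > t_lo) t_lo = alpha[j] - C[j];
      if (alpha[j] < t_hi) t_hi = alpha[j];
    } else {      // a_j_new = a_j + t in [0, C_j]
      if (-alpha[j] > t_lo) t_lo = -alpha[j];
      if (C[j] - alpha[j] < t_hi) t_hi = C[j] - alpha[j];
    }
    if (tstar < t_lo) tstar = t_lo;
    if (tstar > t_hi) tstar = t_hi;
    if (tstar == 0.0) { converged = false; break; }

    double d_i = tstar;
    double d_j = -s * tstar;
    alpha[i] += d_i;
    alpha[j] += d_j;
    // snap to the box to avoid drift
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C[i]) alpha[i] = C[i];
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > C[j]) alpha[j] = C[j];

    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * d_i + y[j] * K(t, j) * d_j);
    }
  }

  // f0_t = sum_j a_j y_j K_tj (decision values without bias)
  NumericVector f0(n);
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int u = 0; u < n; ++u) acc += alpha[u] * y[u] * K(t, u);
    f0[t] = acc;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["f0"] = f0,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
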