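// SMO solver for the soft-margin C-SVC dual with per-sample box constraints:
//
//   min_alpha  0.5 * alpha' Q alpha - e' alpha
//   s.t.       0 <= alpha_i <= C_i,   sum_i alpha_i y_i = 0
//
// with Q_ij = y_i y_j K_ij and K a precomputed kernel matrix. Per-sample
// upper bounds C_i carry the boosting weights into the weak learner
// (C_i = C * n * D_i). Working-set selection is the second-order rule
// (maximal violating pair refined by the quadratic gain), as in libsvm.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, NumericVector C,
               double eps = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("smo_solve: dimension mismatch");
  for (int i = 0; i < n; ++i) {
    if (y[i] != 1 && y[i] != -1) stop("smo_solve: labels must be +1/-1");
    if (!(C[i] > 0)) stop("smo_solve: all C_i must be positive");
  }
  if (max_iter <= 0) {
    max_iter = std::max(10000000 / std::max(n, 1), 200 * n);
    if (max_iter > 4000000) max_iter = 4000000;
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double *Kp = K.begin();

  int iter = 0;
  double gap = std::numeric_limits<double>::infinity();
  for (; iter < max_iter; ++iter) {
    // i: maximal -y_t G_t over I_up
    int i = -1;
    double m = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      if (!up) continue;
      double v = -y[t] * G[t];
      if (v > m) { m = v; i = t; }
    }
    if (i < 0) break;
    const double *Ki = Kp + (size_t)i * n;

    // j: over I_low with violation, minimizing -b^2/a (second-order gain)
    int j = -1;
    double M = std::numeric_limits<double>::infinity();
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C[t]);
      if (!low) continue;
      double v = -y[t] * G[t];
      if (v < M) M = v;
      double b = m - v;
      if (b > 0) {
        double a = Ki[i] + Kp[(size_t)t * n + t] - 2.0 * y[i] * y[t] * Ki[t];
        if (a <= 0) a = TAU;
        double gain = -(b * b) / a;
        if (gain < best) { best = gain; j = t; }
      }
    }
    gap = m - M;
    if (gap < eps || j < 0) break;
    const double *Kj = Kp + (size_t)j * n;

    double Ci = C[i], Cj = C[j];
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      // Q_ii + Q_jj + 2 Q_ij with Q_ij = y_i y_j K_ij = -K_ij here
      double quad = Ki[i] + Kj[j] - 2.0 * (y[i] * y[j]) * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > Ci - Cj) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; }
      } else {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; }
      }
    } else {
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > Cj) {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t) {
        G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
      }
    }
  }

  // bias: average over free SVs of -y_t G_t; fall back to the midpoint of
  // the feasible interval when no SV is strictly inside the box
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 * C[t] && alpha[t] < C[t] * (1 - 1e-8)) {
      b += -y[t] * G[t]; ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C[t]);
      if (up && v > lb) lb = v;
      if (low && v < ub) ub = v;
    }
    b = (std::isfinite(lb) && std::isfinite(ub)) ? (lb + ub) / 2.0 : 0.0;
  }

  // G = Qa - e  =>  0.5 a'Qa - e'a = 0.5 * sum_t a_t (G_t - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (G[t] - 1.0);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter, _["gap"] = gap,
                      _["objective"] = obj);
}
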