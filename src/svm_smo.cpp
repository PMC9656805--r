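#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dual C-SVC solver by sequential minimal optimization with
// maximal-violating-pair working-set selection.
//
// Minimises 0.5 a'Qa - e'a subject to 0 <= a <= C, y'a = 0, where
// Q_ij = y_i y_j K_ij. The gradient G = Qa - e is kept incrementally;
// the stopping rule is the standard KKT violation gap
// max_{I_up}(-yG) - min_{I_low}(-yG) < eps.
//
// Returns alpha, the intercept b (decision value f(x) = sum a_i y_i K(x,x_i)
// + b), the iteration count and a convergence flag. Fully deterministic.

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 500000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("K must be square and match y");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double *Kp = K.begin();
  int iter = 0;
  double gmax = 0.0, gmin = 0.0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    gmax = -1e300; gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] ==  1 && alpha[t] < C) ||
                       (y[t] == -1 && alpha[t] > 0);
      const bool low = (y[t] == -1 && alpha[t] < C) ||
                       (y[t] ==  1 && alpha[t] > 0);
      if (up  && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) { converged = true; break; }

    const double *Ki = Kp + (size_t)i * n;
    const double *Kj = Kp + (size_t)j * n;
    double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (quad <= 0) quad = 1e-12;
    double step = (gmax - gmin) / quad;
    // box constraints: alpha_i += y_i*step, alpha_j -= y_j*step
    double tmax = step;
    tmax = std::min(tmax, (y[i] == 1) ? (C - alpha[i]) : alpha[i]);
    tmax = std::min(tmax, (y[j] == 1) ? alpha[j] : (C - alpha[j]));
    step = std::min(step, tmax);
    if (step <= 0) { converged = true; break; }

    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * step * (Ki[t] - Kj[t]);
  }

  // intercept: average of -y*G over free support vectors, else midpoint
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      bsum += -y[t] * G[t];
      ++nfree;
    }
  }
  double b = (nfree > 0) ? bsum / nfree : 0.5 * (gmax + gmin);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Squared Euclidean distances between rows of A (n x d) and B (m x d).
// [[Rcpp::export]]
NumericMatrix row_sq_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch");
  NumericMatrix D(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      D(i, j) = s;
    }
  }
  return D;
}
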