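#include <Rcpp.h>
using namespace Rcpp;

// RBF kernel matrix K(x, z) = exp(-gamma * ||x - z||^2), rows of X1 vs rows
// of X2. Dense; problem sizes here are <= ~1300 rows x ~250 columns.
// [[Rcpp::export]]
NumericMatrix rbf_kernel(NumericMatrix X1, NumericMatrix X2, double gamma) {
  const int n1 = X1.nrow(), n2 = X2.nrow(), p = X1.ncol();
  if (X2.ncol() != p) stop("rbf_kernel: column mismatch");
  NumericMatrix K(n1, n2);
  std::vector<double> sq1(n1), sq2(n2);
  for (int i = 0; i < n1; ++i) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += X1(i, k) * X1(i, k);
    sq1[i] = s;
  }
  for (int j = 0; j < n2; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += X2(j, k) * X2(j, k);
    sq2[j] = s;
  }
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dot = 0.0;
      for (int k = 0; k < p; ++k) dot += X1(i, k) * X2(j, k);
      double d2 = sq1[i] + sq2[j] - 2.0 * dot;
      if (d2 < 0.0) d2 = 0.0;
      K(i, j) = std::exp(-gamma * d2);
    }
  }
  return K;
}

// Sequential minimal optimisation for the binary soft-margin SVM dual
//   min_a 1/2 a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//   s.t. 0 <= a_i <= C, y' a = 0,
// using maximal-violating-pair working-set selection. Deterministic for a
// given input ordering. Returns alpha, rho (decision = sum a_i y_i K_i. -
// rho), the dual objective, iteration count and convergence flag.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("smo_solve: dimension mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // select maximal violating pair
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) { converged = true; break; }

    // two-variable analytic update
    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a < TAU) a = TAU;
    double delta = (Gmax - Gmin) / a;  // = (-y_i G_i + y_j G_j)/a
    double old_ai = alpha[i], old_aj = alpha[j];
    double ai = old_ai + y[i] * delta;
    double aj = old_aj - y[j] * delta;
    // project back onto the box keeping y_i a_i + y_j a_j constant
    if (y[i] * y[j] > 0) {
      double s = old_ai + old_aj;
      double L = std::max(0.0, s - C), H = std::min(C, s);
      if (ai < L) ai = L; else if (ai > H) ai = H;
      aj = s - ai;
    } else {
      double d = old_ai - old_aj;
      double L = std::max(0.0, d), H = std::min(C, C + d);
      if (ai < L) ai = L; else if (ai > H) ai = H;
      aj = ai - d;
    }
    double dai = ai - old_ai, daj = aj - old_aj;
    if (std::abs(dai) < 1e-16 && std::abs(daj) < 1e-16) {
      converged = true;  // numerically stuck at optimum
      break;
    }
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    ++iter;
  }

  // rho from free support vectors, else midpoint of the violating bounds
  double rho, sum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) { sum += y[t] * G[t]; ++nfree; }
  }
  if (nfree > 0) {
    rho = sum / nfree;
  } else {
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = y[t] * G[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up) lb = std::max(lb, -(-v));  // -(-yG) = yG
    }
    // fall back to midpoint of m/M in the -yG scale
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) Gmax = v;
      if (low && v < Gmin) Gmin = v;
    }
    rho = -(Gmax + Gmin) / 2.0;
    (void)lb; (void)ub;
  }

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj /= 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["objective"] = obj,
                      _["iterations"] = iter, _["converged"] = converged);
}
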