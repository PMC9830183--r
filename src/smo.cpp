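#include <Rcpp.h>
using namespace Rcpp;

// C-classification SVM dual solver on a precomputed kernel matrix.
// Maximal-violating-pair working set selection (LIBSVM WSS1), analytic
// two-variable update. Small-n problems only: the kernel is dense in memory.
//
// Dual: min_a 0.5 * sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//       s.t. sum_i a_i y_i = 0, 0 <= a_i <= C.

// [[Rcpp::export]]
List smo_csvc(NumericMatrix K, IntegerVector y, double C,
              double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix must be square and match label length");

  std::vector<double> alpha(n, 0.0);
  // grad_i = d/d a_i = sum_j a_j y_i y_j K_ij - 1; starts at -1.
  std::vector<double> grad(n, -1.0);

  int iter = 0;
  while (iter < max_iter) {
    // second-order working set selection (LIBSVM WSS2):
    // i maximizes -y_i grad_i over I_up; j minimizes -b^2/a over violating
    // members of I_low.
    // I_up: (y=+1 & a<C) or (y=-1 & a>0)
    // I_low: (y=+1 & a>0) or (y=-1 & a<C)
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up && v > gmax) { gmax = v; i = t; }
    }
    if (i < 0) break;
    double best_obj = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!lo) continue;
      if (v < gmin) gmin = v;
      double b_it = gmax - v;
      if (b_it > 0) {
        // curvature along the feasible pair direction; label terms cancel
        double a_it = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (a_it <= 0) a_it = 1e-12;
        double obj = -(b_it * b_it) / a_it;
        if (obj < best_obj) { best_obj = obj; j = t; }
      }
    }
    if (j < 0 || gmax - gmin < eps) break;

    const double yi = y[i], yj = y[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;

    const double ai_old = alpha[i], aj_old = alpha[j];
    // unconstrained step along the feasible direction
    double delta = (-yi * grad[i] + yj * grad[j]) / quad;
    double ai = ai_old + yi * delta;
    double aj = aj_old - yj * delta;

    // clip to the box, preserving yi*ai + yj*aj
    double sum = yi * ai_old + yj * aj_old;
    if (ai < 0) ai = 0; else if (ai > C) ai = C;
    aj = yj * (sum - yi * ai);
    if (aj < 0) { aj = 0; ai = yi * (sum - yj * aj); }
    else if (aj > C) { aj = C; ai = yi * (sum - yj * aj); }
    if (ai < 0) ai = 0; else if (ai > C) ai = C;

    const double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) break;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (yi * dai * K(i, t) + yj * daj * K(j, t));
    alpha[i] = ai; alpha[j] = aj;
    ++iter;
  }

  // rho: average of -y*grad over free SVs, else midpoint of the bounds
  double rho = 0.0; int nfree = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * grad[t];
    bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { rho += v; ++nfree; }
    if (up && v < ub) ub = v;
    if (lo && v > lb) lb = v;
  }
  rho = (nfree > 0) ? rho / nfree : (ub + lb) / 2.0;
  rho = -rho;  // f(x) = sum_i coef_i K(x_i,x) - rho, LIBSVM convention

  NumericVector coef(n);  // alpha_i * y_i
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coef, _["rho"] = rho,
                      _["iter"] = iter);
}

// Decision values f(x) = sum_i coef_i K(x_i, x) - rho for columns of Ktx
// (rows = training points, cols = test points).

// [[Rcpp::export]]
NumericVector smo_decision(NumericMatrix Ktx, NumericVector coef, double rho) {
  const int n = Ktx.nrow(), m = Ktx.ncol();
  if (coef.size() != n) stop("coef length must match kernel rows");
  NumericVector f(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += coef[i] * Ktx(i, j);
    f[j] = s - rho;
  }
  return f;
}
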