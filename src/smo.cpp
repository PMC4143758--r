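#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
//   min_a  0.5 a'Qa - e'a   s.t.  y'a = 0,  0 <= a_i <= C,
// with Q_ij = y_i y_j K_ij.  Working-set selection is the maximal
// violating pair; convergence when m(a) - M(a) < eps (the usual
// first-order optimality gap).  K must be symmetric PSD.

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("labels must match kernel dimension");

  std::vector<double> alpha(n, 0.0);
  // gradient of the minimization objective at a = 0 is -e
  std::vector<double> grad(n, -1.0);

  int iter = 0;
  double gap = R_PosInf;
  const double TAU = 1e-12;

  while (iter < max_iter) {
    // maximal violating pair
    double m = R_NegInf, M = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      const double v = -y[t] * grad[t];
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    gap = m - M;
    if (i < 0 || j < 0 || gap < eps) break;

    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * y[i] * y[j] * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (-grad[i] - grad[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * y[i] * y[j] * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (grad[i] - grad[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old;
    const double daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    ++iter;
  }

  // dual (maximization) objective W(a) = e'a - 0.5 a'Qa, using
  // a'Qa = a'(grad + e)
  double sum_a = 0.0, ag = 0.0;
  for (int t = 0; t < n; ++t) {
    sum_a += alpha[t];
    ag += alpha[t] * grad[t];
  }
  const double objective = 0.5 * sum_a - 0.5 * ag;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["objective"] = objective);
}
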