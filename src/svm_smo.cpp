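// RBF kernel evaluation and a dual C-SVC solver (SMO with maximal-violating-pair
// working-set selection).  These sit in the inner loop of the wrapper fitness:
// every candidate feature mask costs K_fold * C binary SVM fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// exp(-gamma * ||a_i - b_j||^2) for all row pairs of A (n x d) and B (m x d).
// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
arma::mat rbf_kernel_cpp(const arma::mat& A, const arma::mat& B, double gamma) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * (A * B.t());
  D.each_col() += an;
  D.each_row() += bn.t();
  // clip tiny negative distances from cancellation
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return arma::exp(-gamma * D);
}

// Binary C-SVC on a precomputed kernel.  Solves
//   min_a 1/2 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,  Q_ij = y_i y_j K_ij
// by SMO; working pair = Keerthi's maximal violating pair; stops when the
// KKT gap M_up - M_low < tol.  y must be +/-1.  Returns coef = a*y and the
// intercept b so that f(x) = sum_i coef_i K(x_i, x) + b.
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(const arma::mat& K, const arma::vec& y, double C,
                 double tol = 1e-3, int max_iter = 0) {
  const int n = K.n_rows;
  if (max_iter <= 0) max_iter = std::max(20000, 100 * n);
  arma::vec alpha(n, arma::fill::zeros);
  // F_i = sum_l alpha_l y_l K_il ; dual gradient is y_i F_i - 1
  arma::vec F(n, arma::fill::zeros);

  int iter = 0;
  double M_up = 0.0, M_low = 0.0;
  for (; iter < max_iter; ++iter) {
    // select i in I_up maximizing y_i - F_i, j in I_low minimizing y_j - F_j
    int i = -1, j = -1;
    M_up = -arma::datum::inf;
    M_low = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      double g = y[t] - F[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && g > M_up) { M_up = g; i = t; }
      if (lo && g < M_low) { M_low = g; j = t; }
    }
    if (i < 0 || j < 0 || M_up - M_low < tol) break;

    double ai = alpha[i], aj = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    if (H - L < 1e-12) {  // pair cannot move; treat as converged enough
      break;
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    // E_i - E_j = (F_i - y_i) - (F_j - y_j)
    double aj_new = aj + y[j] * ((F[i] - y[i]) - (F[j] - y[j])) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    if (std::abs(aj_new - aj) < 1e-14) break;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);

    double di = (ai_new - ai) * y[i];
    double dj = (aj_new - aj) * y[j];
    F += di * K.col(i) + dj * K.col(j);
    alpha[i] = ai_new;
    alpha[j] = aj_new;
  }

  // intercept: mean of y_i - F_i over free SVs, else midpoint of the bounds
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += y[t] - F[t];
      ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    b = 0.5 * (M_up + M_low);
    if (!std::isfinite(b)) b = 0.0;
  }

  return List::create(_["coef"] = alpha % y, _["b"] = b,
                      _["iterations"] = iter);
}
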