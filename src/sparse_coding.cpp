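// Orthogonal matching pursuit, batch form. The greedy atom search and the
// per-support least-squares refits dominate pipeline runtime (hundreds of
// thousands of candidate patches per segmentation), hence C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Greedy OMP for one signal. D is m x t with unit-norm columns. Writes the
// selected support (0-based) and coefficients; returns the residual norm.
static double omp_single(const arma::mat& D, const arma::vec& y, int T0,
                         double tol, arma::uvec& support, arma::vec& coef) {
  const int t = D.n_cols;
  arma::vec residual = y;
  std::vector<arma::uword> sel;
  sel.reserve(T0);
  arma::vec c;
  double rnorm = arma::norm(residual, 2);
  for (int step = 0; step < T0; ++step) {
    if (rnorm <= tol) break;
    arma::vec corr = D.t() * residual;
    // strict > keeps the lowest index on ties
    int best = -1;
    double bestval = -1.0;
    for (int j = 0; j < t; ++j) {
      double a = std::fabs(corr[j]);
      if (a > bestval) { bestval = a; best = j; }
    }
    if (best < 0 || bestval <= 1e-12 * std::max(1.0, rnorm)) break;
    // skip atoms already selected (can happen only through numerical noise)
    bool dup = false;
    for (arma::uword s : sel) if ((int)s == best) { dup = true; break; }
    if (dup) break;
    sel.push_back((arma::uword)best);
    arma::uvec idx(sel);
    arma::mat Ds = D.cols(idx);
    if (!arma::solve(c, Ds.t() * Ds, Ds.t() * y, arma::solve_opts::likely_sympd)) {
      arma::solve(c, Ds, y);  // fall back to least squares
    }
    residual = y - Ds * c;
    rnorm = arma::norm(residual, 2);
  }
  support = arma::uvec(sel);
  coef = (sel.empty()) ? arma::vec() : c;
  return rnorm;
}

//' @noRd
// [[Rcpp::export(name = ".ompBatchCpp")]]
List ompBatchCpp(const arma::mat& D, const arma::mat& Y, int T0, double tol) {
  const int t = D.n_cols, N = Y.n_cols;
  arma::mat X(t, N, arma::fill::zeros);
  arma::vec rnorm(N);
  arma::uvec support;
  arma::vec coef;
  for (int i = 0; i < N; ++i) {
    rnorm[i] = omp_single(D, Y.col(i), T0, tol, support, coef);
    for (arma::uword k = 0; k < support.n_elem; ++k)
      X(support[k], i) = coef[k];
  }
  return List::create(_["codes"] = X, _["residuals"] = rnorm);
}

//' @noRd
// [[Rcpp::export(name = ".reconErrorsCpp")]]
arma::vec reconErrorsCpp(const arma::mat& D, const arma::mat& Y, int T0,
                         double tol) {
  const int N = Y.n_cols;
  arma::vec rnorm(N);
  arma::uvec support;
  arma::vec coef;
  for (int i = 0; i < N; ++i)
    rnorm[i] = omp_single(D, Y.col(i), T0, tol, support, coef);
  return rnorm;
}
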