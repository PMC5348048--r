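#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Huber IRLS core used by the no-intercept difference regressions.
// MAD residual scale (consistency constant 0.6745), weights min(1, k*s/|r|).
// Returns the coefficient vector, a convergence flag and the iteration count.
// [[Rcpp::export(name = ".irls_huber")]]
List irls_huber(const arma::mat& X, const arma::vec& y,
                int max_iter, double tol, double k) {
  const arma::uword q = X.n_rows, v = X.n_cols;
  if (q <= v) stop("underdetermined fit");
  arma::vec beta;
  if (!arma::solve(beta, X, y, arma::solve_opts::no_approx)) {
    stop("singular design matrix in robust fit");
  }
  double ymax = arma::abs(y).max();
  bool converged = false;
  int used = 0;
  for (int it = 0; it < max_iter; ++it) {
    used = it + 1;
    arma::vec r = y - X * beta;
    double s = arma::median(arma::abs(r)) / 0.6745;
    if (s < 1e-10 * ymax) { converged = true; break; }  // (near-)exact fit
    arma::vec w = arma::min(arma::ones<arma::vec>(q),
                            k * s / arma::clamp(arma::abs(r), 1e-300, arma::datum::inf));
    arma::vec sw = arma::sqrt(w);
    arma::mat Xw = X.each_col() % sw;
    arma::vec beta_new;
    if (!arma::solve(beta_new, Xw, y % sw, arma::solve_opts::no_approx)) {
      stop("singular weighted design matrix in robust fit");
    }
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol * std::max(1.0, arma::abs(beta).max())) { converged = true; break; }
  }
  return List::create(_["coefficients"] = beta,
                      _["converged"] = converged,
                      _["iterations"] = used);
}
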