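// Batched solve of per-voxel 7x7 symmetric normal equations for the weighted
// log-linear tensor fit. A holds, per voxel, the 28 unique entries of
// X' W X (upper triangle, column-major pair order produced by R), b the 7
// entries of X' W y.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".batch_solve_sym7")]]
arma::mat batch_solve_sym7(const arma::mat& A, const arma::mat& b,
                           const arma::umat& pairs) {
  const arma::uword V = A.n_rows;
  if (b.n_rows != V) Rcpp::stop("A and b row counts differ");
  if (pairs.n_rows != A.n_cols || pairs.n_cols != 2)
    Rcpp::stop("pairs must be n_entries x 2");
  arma::mat out(V, 7, arma::fill::zeros);
  arma::mat M(7, 7);
  arma::vec rhs(7), beta(7);
  for (arma::uword v = 0; v < V; ++v) {
    for (arma::uword k = 0; k < pairs.n_rows; ++k) {
      arma::uword i = pairs(k, 0), j = pairs(k, 1);
      M(i, j) = A(v, k);
      M(j, i) = A(v, k);
    }
    for (arma::uword k = 0; k < 7; ++k) rhs(k) = b(v, k);
    bool ok = arma::solve(beta, M, rhs, arma::solve_opts::likely_sympd +
                                        arma::solve_opts::no_approx);
    if (!ok) beta.fill(arma::datum::nan);
    out.row(v) = beta.t();
  }
  return out;
}
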