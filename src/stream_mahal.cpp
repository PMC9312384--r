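// Streaming expanding-moment squared Mahalanobis distance.
//
// Maintains the running mean and (Welford) centered sum-of-products of all
// valid feature rows seen so far and, once min_history valid rows have
// accumulated, scores each row against the moments that INCLUDE it
// (mu_t, Sigma_t are computed from rows 1..t, never from the future).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector stream_mahal_cpp(const arma::mat& Y,
                                     const Rcpp::LogicalVector& valid,
                                     const int min_history,
                                     const double ridge_frac) {
  const uword n = Y.n_rows, d = Y.n_cols;
  vec mu(d, fill::zeros);
  mat C(d, d, fill::zeros);  // centered sum of outer products
  Rcpp::NumericVector out(n, NA_REAL);
  double k = 0.0;
  const mat I = eye<mat>(d, d);

  for (uword i = 0; i < n; ++i) {
    if (valid[i] == NA_LOGICAL || !valid[i]) continue;
    vec y = Y.row(i).t();
    k += 1.0;
    vec delta = y - mu;
    mu += delta / k;
    C += delta * (y - mu).t();
    if (k < min_history) continue;

    mat S = C / (k - 1.0);
    double md = mean(S.diag());
    // relative ridge keeps early near-constant columns (e.g. integer SCR
    // counts) from making Sigma singular
    double eps = ridge_frac * (md > 0.0 ? md : 1.0);
    vec dev = y - mu;
    vec sol;
    bool ok = solve(sol, S + eps * I, dev, solve_opts::no_approx);
    if (!ok) {
      Rcpp::stop("covariance singular after ridge regularization at row %d "
                 "(rcond = %g)", (int)(i + 1), rcond(S + eps * I));
    }
    double v = dot(dev, sol);
    out[i] = (v < 0.0) ? 0.0 : v;
  }
  return out;
}
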