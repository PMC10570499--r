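// Time-lagged covariance matrices C(tau) = (1/T) sum_t x(t) x(t+tau)^T over
// a common summation window T = N - max(tau), computed as one BLAS product
// per lag on submatrix views (no copies of the data).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::cube lagged_cov_cpp(const arma::mat& x, const arma::uvec& lags) {
  const uword n = x.n_rows, N = x.n_cols;
  const uword maxlag = lags.max();
  if (maxlag >= N) Rcpp::stop("lag >= sample count");
  const uword T = N - maxlag;
  cube out(n, n, lags.n_elem);
  const mat lead = x.cols(0, T - 1);
  for (uword k = 0; k < lags.n_elem; ++k) {
    const uword l = lags[k];
    out.slice(k) = lead * x.cols(l, l + T - 1).t() / double(T);
  }
  return out;
}
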