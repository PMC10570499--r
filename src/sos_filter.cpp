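// Zero-phase (forward-backward) biquad cascade over the channels of a
// samples-x-channels matrix, with reflective end padding so the slow
// high-pass transient never reaches the data.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void biquad_forward(double* x, const uword n,
                           const double* b, const double* a) {
  // direct form II transposed, zero initial state
  double z1 = 0.0, z2 = 0.0;
  for (uword i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z1;
    z1 = b[1] * xi - a[1] * yi + z2;
    z2 = b[2] * xi - a[2] * yi;
    x[i] = yi;
  }
}

// B, A: 3 x n_sections (one biquad per column, a0 normalized to 1)
// [[Rcpp::export]]
arma::mat sos_filtfilt_cpp(const arma::mat& X, const arma::mat& B,
                           const arma::mat& A, int pad) {
  const uword n = X.n_rows, nc = X.n_cols, ns = B.n_cols;
  const uword p = std::min<uword>(pad, n - 1);
  mat out(n, nc);
  vec buf(n + 2 * p);
  double* bp = buf.memptr();
  const uword m = buf.n_elem;
  for (uword c = 0; c < nc; ++c) {
    const double* x = X.colptr(c);
    for (uword i = 0; i < p; ++i) bp[i] = 2.0 * x[0] - x[p - i];
    std::copy(x, x + n, bp + p);
    for (uword i = 0; i < p; ++i) bp[p + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
    for (uword s = 0; s < ns; ++s) {
      biquad_forward(bp, m, B.colptr(s), A.colptr(s));
      std::reverse(bp, bp + m);
      biquad_forward(bp, m, B.colptr(s), A.colptr(s));
      std::reverse(bp, bp + m);
    }
    out.col(c) = buf.subvec(p, p + n - 1);
  }
  return out;
}
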