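// Zero-phase IIR filtering of multichannel signals: direct-form-II
// transposed filter run forward, then backward, per channel (the classic
// filtfilt scheme with end zero-padding to flush the filter state).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

void filt1(const arma::vec& b, const arma::vec& a, const double* x,
           double* y, arma::uword n) {
  const arma::uword nb = b.n_elem, na = a.n_elem;
  const arma::uword nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (arma::uword i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz ? z[0] : 0.0);
    for (arma::uword k = 1; k <= nz; ++k) {
      double zb = (k < nb) ? b[k] * xi : 0.0;
      double za = (k < na) ? a[k] * yi : 0.0;
      z[k - 1] = zb - za + ((k < nz) ? z[k] : 0.0);
    }
    y[i] = yi;
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".filtfiltCpp")]]
arma::mat filtfilt_cpp(arma::vec b, arma::vec a, arma::mat x) {
  if (a.n_elem == 0 || a[0] == 0) Rcpp::stop("a[1] must be nonzero");
  b /= a[0];
  a /= a[0];
  const arma::uword n = x.n_cols;
  const arma::uword pad = 2 * std::max(a.n_elem, b.n_elem);
  arma::mat out(x.n_rows, n);
  std::vector<double> buf(n + pad), tmp(n + pad);
  for (arma::uword ch = 0; ch < x.n_rows; ++ch) {
    for (arma::uword i = 0; i < n; ++i) buf[i] = x(ch, i);
    std::fill(buf.begin() + n, buf.end(), 0.0);
    filt1(b, a, buf.data(), tmp.data(), n + pad);          // forward
    std::reverse(tmp.begin(), tmp.end());
    filt1(b, a, tmp.data(), buf.data(), n + pad);          // backward
    std::reverse(buf.begin(), buf.end());
    for (arma::uword i = 0; i < n; ++i) out(ch, i) = buf[i];
  }
  return out;
}
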