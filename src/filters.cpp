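#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with zero initial conditions.
// Coefficients must be normalized so a[0] == 1. Continuous recordings run
// to ~40 M samples, where R-level filtering loops dominate the pipeline.
// [[Rcpp::export]]
NumericVector iirFilterC(NumericVector b, NumericVector a, NumericVector x) {
  const R_xlen_t n = x.size();
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na);
  std::vector<double> bp(nw, 0.0), ap(nw, 0.0), w(nw, 0.0);
  for (int j = 0; j < nb; ++j) bp[j] = b[j];
  for (int j = 0; j < na; ++j) ap[j] = a[j];
  NumericVector y(n);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  if (nw < 2) {
    for (R_xlen_t i = 0; i < n; ++i) yp[i] = bp[0] * xp[i];
    return y;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bp[0] * xi + w[0];
    for (int j = 1; j < nw - 1; ++j)
      w[j - 1] = bp[j] * xi - ap[j] * yi + w[j];
    w[nw - 2] = bp[nw - 1] * xi - ap[nw - 1] * yi;
    yp[i] = yi;
  }
  return y;
}
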