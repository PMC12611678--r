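#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Direct-form II transposed IIR filter with initial state; a[0] must be 1.
// Inner loop of the zero-phase (forward-backward) filtering in R/filters.R.
// [[Rcpp::export]]
arma::vec lfilter_cpp(const arma::vec& b, const arma::vec& a,
                      const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem;
  const int m = std::max(a.n_elem, b.n_elem);
  vec bb(m, fill::zeros), aa(m, fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  vec z(m - 1, fill::zeros);
  if (zi.n_elem > 0) z.head(zi.n_elem) = zi;
  vec y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x(i);
    const double yi = bb(0) * xi + z(0);
    for (int j = 0; j < m - 2; ++j)
      z(j) = bb(j + 1) * xi + z(j + 1) - aa(j + 1) * yi;
    z(m - 2) = bb(m - 1) * xi - aa(m - 1) * yi;
    y(i) = yi;
  }
  return y;
}
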