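#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections, direct form II transposed, zero initial state.
// b, a: n_sections x 3 coefficient matrices with a(,0) == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericVector x, NumericMatrix b, NumericMatrix a) {
  int n = x.size();
  int ns = b.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = b(s, 0), b1 = b(s, 1), b2 = b(s, 2);
    double a1 = a(s, 1), a2 = a(s, 2);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
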