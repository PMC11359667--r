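#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter with initial state zi (length nf-1).
// b and a must be padded to common length nf with a[0] == 1.
// [[Rcpp::export]]
List cpp_lfilter(NumericVector b, NumericVector a, NumericVector x,
                 NumericVector zi) {
  const int n = x.size();
  const int nf = b.size();
  if (a.size() != nf) stop("b and a must have equal length");
  if (zi.size() != nf - 1) stop("zi must have length(b) - 1 elements");
  NumericVector z = clone(zi);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = z);
}
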