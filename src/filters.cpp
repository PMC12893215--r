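#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial state. b and a must be
// padded to equal length with a[0] == 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int n = x.size(), m = b.size();
  std::vector<double> z(m - 1, 0.0);
  for (int j = 0; j < (int)zi.size() && j < m - 1; ++j) z[j] = zi[j];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}
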