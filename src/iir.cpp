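// Direct-form-II transposed IIR filtering; coefficient design stays in R
// (signal::butter), only the sample recursion runs here.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector iir_filter_cpp(const NumericVector& b, const NumericVector& a,
                             const NumericVector& x,
                             const NumericVector& winit) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  for (int j = 0; j < winit.size() && j < nw; ++j) w[j] = winit[j];
  NumericVector y(n);
  double a0 = a[0];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = (b[0] * xi + w[0]) / a0;
    for (int j = 1; j < nw; ++j) {
      double bj = j < nb ? b[j] : 0.0;
      double aj = j < na ? a[j] : 0.0;
      w[j - 1] = bj * xi - aj * yi + (j < nw - 1 ? w[j] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
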