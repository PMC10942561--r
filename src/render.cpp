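// Sum of minimum-jerk submovement contributions and their analytic
// derivatives on a uniform time grid.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List render_kernels_cpp(const NumericVector& starts, const NumericVector& durs,
                        const NumericMatrix& disp, const NumericVector& t) {
  int n = t.size(), K = starts.size();
  NumericMatrix pos(n, 3), vel(n, 3), acc(n, 3), jerk(n, 3);
  for (int k = 0; k < K; ++k) {
    double st = starts[k], d = durs[k], en = st + d;
    for (int i = 0; i < n; ++i) {
      double ti = t[i];
      if (ti <= st) continue;
      if (ti >= en) {
        for (int j = 0; j < 3; ++j) pos(i, j) += disp(k, j);
        continue;
      }
      double tau = (ti - st) / d;
      double s = tau * tau * tau * (10.0 - 15.0 * tau + 6.0 * tau * tau);
      double u = 1.0 - tau;
      double s1 = 30.0 * tau * tau * u * u / d;
      double s2 = 60.0 * tau * u * (1.0 - 2.0 * tau) / (d * d);
      double s3 = (60.0 - 360.0 * tau + 360.0 * tau * tau) / (d * d * d);
      for (int j = 0; j < 3; ++j) {
        double dj = disp(k, j);
        pos(i, j) += s * dj;
        vel(i, j) += s1 * dj;
        acc(i, j) += s2 * dj;
        jerk(i, j) += s3 * dj;
      }
    }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["acc"] = acc,
                      _["jerk"] = jerk);
}
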