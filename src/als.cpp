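#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric least squares baseline (Eilers-style): iterate
//   z = argmin  sum_i w_i (y_i - z_i)^2 + lam * sum (d2 z)^2
// with w_i = p where y_i > z_i, 1-p otherwise. The normal equations
// (W + lam * D2'D2) z = W y are pentadiagonal; solved by banded Cholesky.
// Y: bands x npix matrix (one spectrum per column). Returns baselines,
// same shape.
// [[Rcpp::export]]
NumericMatrix als_batch_(NumericMatrix Y, double lam, double p, int n_iter) {
  int n = Y.nrow(), m = Y.ncol();
  NumericMatrix Z(n, m);
  if (n < 3) stop("ALS needs at least 3 bands");

  // penalty band structure of D2'D2 (constant across pixels)
  std::vector<double> p0(n, 0.0), p1(n, 0.0), p2(n, 0.0);
  for (int k = 0; k + 2 < n; ++k) {
    p0[k] += 1.0; p0[k + 1] += 4.0; p0[k + 2] += 1.0;
    p1[k] += -2.0; p1[k + 1] += -2.0;
    p2[k] += 1.0;
  }

  std::vector<double> w(n), a0(n), a1(n), a2(n), l0(n), l1(n), l2(n), x(n), z(n);
  for (int j = 0; j < m; ++j) {
    const double *y = &Y(0, j);
    std::fill(w.begin(), w.end(), 1.0);
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < n; ++i) {
        a0[i] = w[i] + lam * p0[i];
        a1[i] = lam * p1[i];
        a2[i] = lam * p2[i];
      }
      // banded Cholesky A = L L', bandwidth 2
      for (int i = 0; i < n; ++i) {
        double d = a0[i];
        if (i >= 1) d -= l1[i - 1] * l1[i - 1];
        if (i >= 2) d -= l2[i - 2] * l2[i - 2];
        l0[i] = std::sqrt(d);
        if (i + 1 < n) {
          double s = a1[i];
          if (i >= 1) s -= l2[i - 1] * l1[i - 1];
          l1[i] = s / l0[i];
        }
        if (i + 2 < n) l2[i] = a2[i] / l0[i];
      }
      // solve L x = W y, then L' z = x
      for (int i = 0; i < n; ++i) {
        double s = w[i] * y[i];
        if (i >= 1) s -= l1[i - 1] * x[i - 1];
        if (i >= 2) s -= l2[i - 2] * x[i - 2];
        x[i] = s / l0[i];
      }
      for (int i = n - 1; i >= 0; --i) {
        double s = x[i];
        if (i + 1 < n) s -= l1[i] * z[i + 1];
        if (i + 2 < n) s -= l2[i] * z[i + 2];
        z[i] = s / l0[i];
      }
      for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
    }
    for (int i = 0; i < n; ++i) Z(i, j) = z[i];
  }
  return Z;
}
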