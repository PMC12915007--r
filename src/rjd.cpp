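#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joint approximate diagonalization of k real symmetric n x n matrices by
// Jacobi rotations (Cardoso & Souloumiac).  `mats` is an n x n x k array;
// returns the orthogonal matrix V (columns = joint eigenvectors) and the
// rotated matrices V' M V.
// [[Rcpp::export]]
List rjd_cpp(NumericVector mats, int n, int k, double eps = 1e-8,
             int max_sweeps = 100) {
  std::vector<double> a(mats.begin(), mats.end()); // n*n*k, column-major
  NumericMatrix v(n, n);
  for (int i = 0; i < n; ++i) v(i, i) = 1.0;
  const int nn = n * n;
  bool active = true;
  int sweep = 0;
  while (active && sweep < max_sweeps) {
    active = false;
    ++sweep;
    for (int p = 0; p < n - 1; ++p) {
      for (int q = p + 1; q < n; ++q) {
        double g11 = 0.0, g12 = 0.0, g22 = 0.0;
        for (int m = 0; m < k; ++m) {
          double *mm = &a[m * nn];
          double ton = mm[p + n * p] - mm[q + n * q];
          double toff = 2.0 * mm[p + n * q];
          g11 += ton * ton;
          g12 += ton * toff;
          g22 += toff * toff;
        }
        // principal eigenvector of the 2x2 Gram matrix
        double delta = std::sqrt((g11 - g22) * (g11 - g22) + 4.0 * g12 * g12);
        double x = g11 - g22 + delta;
        double y = 2.0 * g12;
        double norm = std::sqrt(x * x + y * y);
        if (norm < 1e-300) continue;
        x /= norm; y /= norm;
        if (x < 0) { x = -x; y = -y; }
        double c = std::sqrt((x + 1.0) / 2.0);
        double s = y / (2.0 * c);
        if (std::fabs(s) > eps) {
          active = true;
          for (int m = 0; m < k; ++m) {
            double *mm = &a[m * nn];
            for (int i = 0; i < n; ++i) { // rotate columns p, q
              double mp = mm[i + n * p], mq = mm[i + n * q];
              mm[i + n * p] = c * mp + s * mq;
              mm[i + n * q] = -s * mp + c * mq;
            }
            for (int i = 0; i < n; ++i) { // rotate rows p, q
              double mp = mm[p + n * i], mq = mm[q + n * i];
              mm[p + n * i] = c * mp + s * mq;
              mm[q + n * i] = -s * mp + c * mq;
            }
          }
          for (int i = 0; i < n; ++i) {
            double vp = v(i, p), vq = v(i, q);
            v(i, p) = c * vp + s * vq;
            v(i, q) = -s * vp + c * vq;
          }
        }
      }
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(n, n, k);
  return List::create(_["v"] = v, _["diagonalized"] = out,
                      _["sweeps"] = sweep);
}
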