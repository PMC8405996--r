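#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information (algorithm 1) between two
// multivariate samples, max-norm throughout.
//
//   I = psi(k) + psi(N) - < psi(n_x + 1) + psi(n_y + 1) >
//
// where eps_i is the max-norm distance from point i to its k-th nearest
// neighbour in the joint (X,Y) space and n_x(i), n_y(i) count points strictly
// within eps_i of point i in each marginal space. Brute-force O(N^2) scan;
// intended sample sizes (<= ~2e4 after subsampling) keep this well under a
// second per pair.
//
// x: N x dx matrix, y: N x dy matrix, k: neighbour order (>=1).
// [[Rcpp::export(name = ".ksg_mi")]]
double ksg_mi(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  const int dx = x.ncol();
  const int dy = y.ncol();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");

  // row-major copies keep the inner scans cache-friendly
  std::vector<double> xr((size_t)n * dx), yr((size_t)n * dy);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dx; ++c) xr[(size_t)i * dx + c] = x(i, c);
    for (int c = 0; c < dy; ++c) yr[(size_t)i * dy + c] = y(i, c);
  }

  std::vector<double> kth(n);

  // pass 1: k-th joint-space neighbour distance per point
  std::vector<double> dj(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * dx];
    const double* yi = &yr[(size_t)i * dy];
    for (int j = 0; j < n; ++j) {
      const double* xj = &xr[(size_t)j * dx];
      const double* yj = &yr[(size_t)j * dy];
      double m = 0.0;
      for (int c = 0; c < dx; ++c) {
        double d = std::fabs(xj[c] - xi[c]);
        if (d > m) m = d;
      }
      for (int c = 0; c < dy; ++c) {
        double d = std::fabs(yj[c] - yi[c]);
        if (d > m) m = d;
      }
      dj[j] = m;
    }
    dj[i] = R_PosInf;  // exclude self
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.end());
    kth[i] = dj[(size_t)k - 1];
  }

  // pass 2: strict marginal neighbour counts within eps_i
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double eps = kth[i];
    const double* xi = &xr[(size_t)i * dx];
    const double* yi = &yr[(size_t)i * dy];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* xj = &xr[(size_t)j * dx];
      double mx = 0.0;
      for (int c = 0; c < dx; ++c) {
        double d = std::fabs(xj[c] - xi[c]);
        if (d > mx) mx = d;
      }
      if (mx < eps) ++nx;
      const double* yj = &yr[(size_t)j * dy];
      double my = 0.0;
      for (int c = 0; c < dy; ++c) {
        double d = std::fabs(yj[c] - yi[c]);
        if (d > my) my = d;
      }
      if (my < eps) ++ny;
    }
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }

  return R::digamma((double)k) + R::digamma((double)n) - acc / (double)n;
}
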