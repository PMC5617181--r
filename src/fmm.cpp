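#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// First-order anisotropic fast marching: solves |grad T| = 1/speed on the
// foreground, T(source)=0. Upwind update with the usual sorted incremental
// quadratic.
static double eikonal_update(const std::vector<double> &a,
                             const std::vector<double> &h, double inv_f) {
  // a: available upwind arrival values, h: matching grid steps
  const int m = (int)a.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) { return a[i] < a[j]; });
  double t = a[ord[0]] + h[ord[0]] * inv_f;
  for (int k = 1; k < m; k++) {
    if (t <= a[ord[k]]) break;
    // solve sum_{i<=k} ((t - a_i)/h_i)^2 = inv_f^2
    double A = 0, B = 0, C = -inv_f * inv_f;
    for (int i = 0; i <= k; i++) {
      double w = 1.0 / (h[ord[i]] * h[ord[i]]);
      A += w;
      B += -2.0 * a[ord[i]] * w;
      C += a[ord[i]] * a[ord[i]] * w;
    }
    double disc = B * B - 4 * A * C;
    if (disc < 0) break;
    t = (-B + std::sqrt(disc)) / (2 * A);
  }
  return t;
}

//' @noRd
// [[Rcpp::export(name = ".fmm3d_cpp")]]
NumericVector fmm3d_cpp(NumericVector speed, IntegerVector dims,
                        NumericVector spacing, IntegerVector sources) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};

  NumericVector T(ntot);
  std::vector<unsigned char> known(ntot, 0);
  for (R_xlen_t i = 0; i < ntot; i++) T[i] = R_PosInf;

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  for (int s = 0; s < sources.size(); s++) {
    R_xlen_t idx = (R_xlen_t)sources[s] - 1; // 1-based from R
    if (idx < 0 || idx >= ntot) stop("source index out of range");
    T[idx] = 0.0;
    heap.push(QE(0.0, idx));
  }

  const R_xlen_t strd[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};

  while (!heap.empty()) {
    QE top = heap.top();
    heap.pop();
    R_xlen_t idx = top.second;
    if (known[idx]) continue; // lazy deletion
    known[idx] = 1;
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    int pos[3] = {z, y, x};
    int dmax[3] = {nz, ny, nx};
    for (int ax = 0; ax < 3; ax++) {
      for (int dir = -1; dir <= 1; dir += 2) {
        int p = pos[ax] + dir;
        if (p < 0 || p >= dmax[ax]) continue;
        R_xlen_t nb = idx + dir * strd[ax];
        if (known[nb]) continue;
        double f = speed[nb];
        if (!(f > 0)) continue; // outside mask
        // gather upwind values for the neighbor
        int npos[3] = {z, y, x};
        npos[ax] = p;
        std::vector<double> a;
        std::vector<double> ah;
        for (int ax2 = 0; ax2 < 3; ax2++) {
          double best = R_PosInf;
          for (int d2 = -1; d2 <= 1; d2 += 2) {
            int q = npos[ax2] + d2;
            if (q < 0 || q >= dmax[ax2]) continue;
            R_xlen_t nn = nb + d2 * strd[ax2];
            if (known[nn] && T[nn] < best) best = T[nn];
          }
          if (R_finite(best)) {
            a.push_back(best);
            ah.push_back(h[ax2]);
          }
        }
        if (a.empty()) continue;
        double t = eikonal_update(a, ah, 1.0 / f);
        if (t < T[nb]) {
          T[nb] = t;
          heap.push(QE(t, nb));
        }
      }
    }
  }
  T.attr("dim") = dims;
  return T;
}
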