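#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1D squared distance transform (lower envelope of parabolas), sample
// positions q*h. f holds squared distances; large finite value = "no site".
static void dt1d(std::vector<double> &f, std::vector<double> &d, double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double xq = q * h;
    double s;
    for (;;) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s > z[k]) break;
      k--;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  // generous finite stand-in for +inf keeps the parabola algebra NaN-free
  double big = 0.0;
  big += (double)nz * hz * (double)nz * hz;
  big += (double)ny * hy * (double)ny * hy;
  big += (double)nx * hx * (double)nx * hx;
  big *= 4.0;

  NumericVector d(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) d[i] = mask[i] ? big : 0.0;

  // z (fastest-varying index)
  {
    std::vector<double> f(nz), o(nz);
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = ((R_xlen_t)x * ny + y) * nz;
        for (int z = 0; z < nz; z++) f[z] = d[base + z];
        dt1d(f, o, hz);
        for (int z = 0; z < nz; z++) d[base + z] = o[z] > big ? big : o[z];
      }
  }
  // y
  {
    std::vector<double> f(ny), o(ny);
    for (int x = 0; x < nx; x++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t base = (R_xlen_t)x * ny * nz + z;
        for (int y = 0; y < ny; y++) f[y] = d[base + (R_xlen_t)y * nz];
        dt1d(f, o, hy);
        for (int y = 0; y < ny; y++)
          d[base + (R_xlen_t)y * nz] = o[y] > big ? big : o[y];
      }
  }
  // x
  {
    std::vector<double> f(nx), o(nx);
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t base = (R_xlen_t)y * nz + z;
        for (int x = 0; x < nx; x++) f[x] = d[base + (R_xlen_t)x * ny * nz];
        dt1d(f, o, hx);
        for (int x = 0; x < nx; x++)
          d[base + (R_xlen_t)x * ny * nz] = o[x] > big ? big : o[x];
      }
  }
  for (R_xlen_t i = 0; i < ntot; i++) d[i] = std::sqrt(d[i]);
  d.attr("dim") = dims;
  return d;
}
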