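#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".label_cc_cpp")]]
IntegerVector label_cc_cpp(LogicalVector mask, IntegerVector dims) {
  // 26-connectivity (8-connectivity when one dim is 1)
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t seed = 0; seed < ntot; seed++) {
    if (!mask[seed] || lab[seed]) continue;
    cur++;
    lab[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx % nz);
      int y = (int)((idx / nz) % ny);
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dz = -1; dz <= 1; dz++) {
            if (!dx && !dy && !dz) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 ||
                x2 >= nx)
              continue;
            R_xlen_t nb = ((R_xlen_t)x2 * ny + y2) * nz + z2;
            if (mask[nb] && !lab[nb]) {
              lab[nb] = cur;
              stack.push_back(nb);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
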