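#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface by marching tetrahedra on the Freudenthal 6-tetrahedron
// decomposition of each grid cell. The decomposition tiles the lattice
// consistently, so shared tet faces/edges between neighboring cells agree and
// the resulting mesh is watertight (every edge on exactly two triangles) for
// an isovalue crossing strictly inside the grid.

struct MTState {
  std::vector<double> V;  // x,y,z triples
  std::vector<int> F;     // 1-based vertex index triples
  std::unordered_map<long long, int> edge_vert;
};

// corner index c: dz = c&1, dy = (c>>1)&1, dx = (c>>2)&1
static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                               {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

//' @noRd
// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dims,
                    NumericVector spacing, double level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  const long long ntot = (long long)nz * ny * nx;
  MTState st;

  // edge-interpolated vertex, deduplicated by global endpoint pair
  auto edge_vertex = [&](long long g1, double v1, long long g2,
                         double v2) -> int {
    if (g1 > g2) {
      std::swap(g1, g2);
      std::swap(v1, v2);
    }
    long long key = g1 * ntot + g2;
    auto it = st.edge_vert.find(key);
    if (it != st.edge_vert.end()) return it->second;
    double t = (level - v1) / (v2 - v1);
    int z1 = (int)(g1 % nz), y1 = (int)((g1 / nz) % ny),
        x1 = (int)(g1 / ((long long)nz * ny));
    int z2 = (int)(g2 % nz), y2 = (int)((g2 / nz) % ny),
        x2 = (int)(g2 / ((long long)nz * ny));
    double px = (x1 + t * (x2 - x1)) * hx;
    double py = (y1 + t * (y2 - y1)) * hy;
    double pz = (z1 + t * (z2 - z1)) * hz;
    st.V.push_back(px);
    st.V.push_back(py);
    st.V.push_back(pz);
    int id = (int)(st.V.size() / 3); // 1-based
    st.edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const double in_c[3],
                  const double out_c[3]) {
    // orient so the normal points from inside (>= level) to outside
    const double *pa = &st.V[(a - 1) * 3], *pb = &st.V[(b - 1) * 3],
                 *pc = &st.V[(c - 1) * 3];
    double u[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
    double v[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
    double n[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                   u[0] * v[1] - u[1] * v[0]};
    double d[3] = {out_c[0] - in_c[0], out_c[1] - in_c[1], out_c[2] - in_c[2]};
    double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dot >= 0) {
      st.F.push_back(a);
      st.F.push_back(b);
      st.F.push_back(c);
    } else {
      st.F.push_back(a);
      st.F.push_back(c);
      st.F.push_back(b);
    }
  };

  long long cg[8];
  double cv[8], cpos[8][3];
  for (int x = 0; x < nx - 1; x++)
    for (int y = 0; y < ny - 1; y++)
      for (int z = 0; z < nz - 1; z++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int dz = c & 1, dy = (c >> 1) & 1, dx = (c >> 2) & 1;
          long long g = ((long long)(x + dx) * ny + (y + dy)) * nz + (z + dz);
          cg[c] = g;
          cv[c] = field[g];
          cpos[c][0] = (x + dx) * hx;
          cpos[c][1] = (y + dy) * hy;
          cpos[c][2] = (z + dz) * hz;
          if (cv[c] >= level)
            any_in = true;
          else
            any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          const int *tc = TETS[t];
          int in_idx[4], out_idx[4];
          int ni = 0, no = 0;
          for (int k = 0; k < 4; k++) {
            if (cv[tc[k]] >= level)
              in_idx[ni++] = tc[k];
            else
              out_idx[no++] = tc[k];
          }
          if (ni == 0 || ni == 4) continue;
          double in_c[3] = {0, 0, 0}, out_c[3] = {0, 0, 0};
          for (int k = 0; k < ni; k++)
            for (int j = 0; j < 3; j++) in_c[j] += cpos[in_idx[k]][j] / ni;
          for (int k = 0; k < no; k++)
            for (int j = 0; j < 3; j++) out_c[j] += cpos[out_idx[k]][j] / no;
          if (ni == 1) {
            int a = edge_vertex(cg[in_idx[0]], cv[in_idx[0]], cg[out_idx[0]],
                                cv[out_idx[0]]);
            int b = edge_vertex(cg[in_idx[0]], cv[in_idx[0]], cg[out_idx[1]],
                                cv[out_idx[1]]);
            int c = edge_vertex(cg[in_idx[0]], cv[in_idx[0]], cg[out_idx[2]],
                                cv[out_idx[2]]);
            emit(a, b, c, in_c, out_c);
          } else if (ni == 3) {
            int a = edge_vertex(cg[out_idx[0]], cv[out_idx[0]], cg[in_idx[0]],
                                cv[in_idx[0]]);
            int b = edge_vertex(cg[out_idx[0]], cv[out_idx[0]], cg[in_idx[1]],
                                cv[in_idx[1]]);
            int c = edge_vertex(cg[out_idx[0]], cv[out_idx[0]], cg[in_idx[2]],
                                cv[in_idx[2]]);
            emit(a, b, c, in_c, out_c);
          } else { // ni == 2: quad split into two triangles
            int a = edge_vertex(cg[in_idx[0]], cv[in_idx[0]], cg[out_idx[0]],
                                cv[out_idx[0]]);
            int b = edge_vertex(cg[in_idx[0]], cv[in_idx[0]], cg[out_idx[1]],
                                cv[out_idx[1]]);
            int c = edge_vertex(cg[in_idx[1]], cv[in_idx[1]], cg[out_idx[1]],
                                cv[out_idx[1]]);
            int d = edge_vertex(cg[in_idx[1]], cv[in_idx[1]], cg[out_idx[0]],
                                cv[out_idx[0]]);
            emit(a, b, c, in_c, out_c);
            emit(a, c, d, in_c, out_c);
          }
        }
      }

  int nv = (int)(st.V.size() / 3);
  int nf = (int)(st.F.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++)
    for (int j = 0; j < 3; j++) V(i, j) = st.V[i * 3 + j];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; i++)
    for (int j = 0; j < 3; j++) F(i, j) = st.F[i * 3 + j];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
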