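#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Triangulate the zero level set of a cell-centred scalar field by marching
// tetrahedra: each dual cube (corners = 8 neighbouring cell centres) is
// split into 6 tetrahedra; the zero crossing inside each tetrahedron is a
// triangle or quad found by linear interpolation along edges.

struct V3 { double x, y, z; };

static V3 lerp0(const V3& a, const V3& b, double fa, double fb) {
  double t = fa / (fa - fb);
  V3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

// [[Rcpp::export]]
NumericMatrix marching_tet_cpp(NumericVector phi, IntegerVector dims,
                               NumericVector h, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  // tetrahedra of the unit cube (corner ordering: bit0=x, bit1=y, bit2=z)
  const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  std::vector<double> tri;  // 9 doubles per triangle
  V3 c[8];
  double f[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyNeg = false, anyPos = false;
        for (int m = 0; m < 8; ++m) {
          int ii = i + (m & 1), jj = j + ((m >> 1) & 1), kk = k + ((m >> 2) & 1);
          f[m] = phi[idx(ii, jj, kk)];
          c[m].x = origin[0] + (ii + 0.5) * h[0];
          c[m].y = origin[1] + (jj + 0.5) * h[1];
          c[m].z = origin[2] + (kk + 0.5) * h[2];
          if (f[m] < 0) anyNeg = true; else anyPos = true;
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int neg[4], pos[4], nn = 0, np = 0;
          for (int m = 0; m < 4; ++m) {
            if (f[T[m]] < 0) neg[nn++] = T[m]; else pos[np++] = T[m];
          }
          if (nn == 0 || np == 0) continue;
          if (nn == 1 || np == 1) {
            int apex = (nn == 1) ? neg[0] : pos[0];
            const int* base = (nn == 1) ? pos : neg;
            V3 p0 = lerp0(c[apex], c[base[0]], f[apex], f[base[0]]);
            V3 p1 = lerp0(c[apex], c[base[1]], f[apex], f[base[1]]);
            V3 p2 = lerp0(c[apex], c[base[2]], f[apex], f[base[2]]);
            double v[9] = {p0.x, p0.y, p0.z, p1.x, p1.y, p1.z, p2.x, p2.y, p2.z};
            tri.insert(tri.end(), v, v + 9);
          } else {
            // 2/2 split: quad with corners e(n0,p0), e(n0,p1), e(n1,p1), e(n1,p0)
            V3 q0 = lerp0(c[neg[0]], c[pos[0]], f[neg[0]], f[pos[0]]);
            V3 q1 = lerp0(c[neg[0]], c[pos[1]], f[neg[0]], f[pos[1]]);
            V3 q2 = lerp0(c[neg[1]], c[pos[1]], f[neg[1]], f[pos[1]]);
            V3 q3 = lerp0(c[neg[1]], c[pos[0]], f[neg[1]], f[pos[0]]);
            double v1[9] = {q0.x, q0.y, q0.z, q1.x, q1.y, q1.z, q2.x, q2.y, q2.z};
            double v2[9] = {q0.x, q0.y, q0.z, q2.x, q2.y, q2.z, q3.x, q3.y, q3.z};
            tri.insert(tri.end(), v1, v1 + 9);
            tri.insert(tri.end(), v2, v2 + 9);
          }
        }
      }
  size_t nt = tri.size() / 9;
  NumericMatrix out(nt, 9);
  for (size_t r = 0; r < nt; ++r)
    for (int q = 0; q < 9; ++q) out(r, q) = tri[9 * r + q];
  return out;
}
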