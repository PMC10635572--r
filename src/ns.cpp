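#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Staggered (MAC) layout, column-major like R:
//   u: (nx+1, ny, nz) at x-faces,  x = i*hx,        y = (j+.5)hy, z = (k+.5)hz
//   v: (nx, ny+1, nz) at y-faces
//   w: (nx, ny, nz+1) at z-faces
//   p, phi, tags: (nx, ny, nz) at cell centres
// For a periodic axis the last face plane duplicates the first and is kept
// in sync by the R driver; kernels index modulo the cell count.

static inline int wrapc(int i, int n, bool per) {
  if (per) { i %= n; if (i < 0) i += n; return i; }
  return std::min(std::max(i, 0), n - 1);
}

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz;
  bool px, py, pz;
};

// access a staggered component; `s` = staggered axis (0,1,2), array dims na*
struct Comp {
  const double* a;
  int n0, n1, n2;  // array dims
  int s;
  const Grid* g;
  inline double at(int i, int j, int k) const {
    // wrap/clamp: along the staggered axis the logical period is the cell
    // count (faces 0..n-1, face n duplicates 0)
    bool per0 = g->px, per1 = g->py, per2 = g->pz;
    int m0 = (s == 0 && per0) ? g->nx : n0;
    int m1 = (s == 1 && per1) ? g->ny : n1;
    int m2 = (s == 2 && per2) ? g->nz : n2;
    i = wrapc(i, m0, per0);
    j = wrapc(j, m1, per1);
    k = wrapc(k, m2, per2);
    return a[(size_t)i + (size_t)n0 * (j + (size_t)n1 * k)];
  }
};

static const double C1_2[3] = {-0.5, 0, 0.5};
static const double C1_4[5] = {1.0 / 12, -2.0 / 3, 0, 2.0 / 3, -1.0 / 12};
static const double C1_6[7] = {-1.0 / 60, 3.0 / 20, -0.75, 0, 0.75, -3.0 / 20, 1.0 / 60};
static const double C2_2[3] = {1, -2, 1};
static const double C2_4[5] = {-1.0 / 12, 4.0 / 3, -2.5, 4.0 / 3, -1.0 / 12};
static const double C2_6[7] = {1.0 / 90, -3.0 / 20, 1.5, -49.0 / 18, 1.5, -3.0 / 20, 1.0 / 90};

static inline double cderiv(const Comp& c, int i, int j, int k, int axis,
                            int deriv, int order, double h) {
  int half = order / 2;
  const double* cf =
    (deriv == 1) ? (order == 2 ? C1_2 : (order == 4 ? C1_4 : C1_6))
                 : (order == 2 ? C2_2 : (order == 4 ? C2_4 : C2_6));
  double s = 0;
  for (int m = -half; m <= half; ++m) {
    double f = (axis == 0) ? c.at(i + m, j, k)
             : (axis == 1) ? c.at(i, j + m, k) : c.at(i, j, k + m);
    s += cf[m + half] * f;
  }
  return (deriv == 1) ? s / h : s / (h * h);
}

// order per cell (2/4/6), clamped access
static inline int cellOrder(const IntegerVector& ord, const Grid& g,
                            int i, int j, int k) {
  i = wrapc(i, g.nx, g.px); j = wrapc(j, g.ny, g.py); k = wrapc(k, g.nz, g.pz);
  return ord[(size_t)i + (size_t)g.nx * (j + (size_t)g.ny * k)];
}

// [[Rcpp::export]]
List ns_rhs_cpp(NumericVector u, NumericVector v, NumericVector w,
                IntegerVector dims, NumericVector h, LogicalVector periodic,
                double invRe, IntegerVector orderCell, NumericVector force) {
  Grid g{dims[0], dims[1], dims[2], h[0], h[1], h[2],
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  int nx = g.nx, ny = g.ny, nz = g.nz;
  Comp U{REAL(u), nx + 1, ny, nz, 0, &g};
  Comp V{REAL(v), nx, ny + 1, nz, 1, &g};
  Comp W{REAL(w), nx, ny, nz + 1, 2, &g};
  NumericVector Fu((size_t)(nx + 1) * ny * nz);
  NumericVector Fv((size_t)nx * (ny + 1) * nz);
  NumericVector Fw((size_t)nx * ny * (nz + 1));

  // Advection in skew-symmetric form, N = -1/2 (u.grad u + div(u u)),
  // second order on the MAC lattice: discretely energy-conserving for
  // divergence-free fields, which keeps the non-dissipative central scheme
  // stable on coarse grids. Diffusion uses centred stencils of the
  // configured order (reduced near walls/fringes via orderCell).

  // u faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int o = std::min(cellOrder(orderCell, g, i - 1, j, k),
                         cellOrder(orderCell, g, i, j, k));
        double ua = U.at(i, j, k);
        // cell-centred u left/right of the face
        double ucL = 0.5 * (U.at(i - 1, j, k) + ua);
        double ucR = 0.5 * (ua + U.at(i + 1, j, k));
        // transported u and transporting v/w at the face corners
        double vaL = 0.5 * (V.at(i - 1, j, k) + V.at(i, j, k));
        double vaR = 0.5 * (V.at(i - 1, j + 1, k) + V.at(i, j + 1, k));
        double uaL = 0.5 * (U.at(i, j - 1, k) + ua);
        double uaR = 0.5 * (ua + U.at(i, j + 1, k));
        double waL = 0.5 * (W.at(i - 1, j, k) + W.at(i, j, k));
        double waR = 0.5 * (W.at(i - 1, j, k + 1) + W.at(i, j, k + 1));
        double uaB = 0.5 * (U.at(i, j, k - 1) + ua);
        double uaT = 0.5 * (ua + U.at(i, j, k + 1));
        double divf = (ucR * ucR - ucL * ucL) / g.hx +
                      (vaR * uaR - vaL * uaL) / g.hy +
                      (waR * uaT - waL * uaB) / g.hz;
        double advf = ua * (U.at(i + 1, j, k) - U.at(i - 1, j, k)) / (2 * g.hx) +
          0.5 * (vaL + vaR) * (U.at(i, j + 1, k) - U.at(i, j - 1, k)) / (2 * g.hy) +
          0.5 * (waL + waR) * (U.at(i, j, k + 1) - U.at(i, j, k - 1)) / (2 * g.hz);
        double dif = cderiv(U, i, j, k, 0, 2, o, g.hx) +
                     cderiv(U, i, j, k, 1, 2, o, g.hy) +
                     cderiv(U, i, j, k, 2, 2, o, g.hz);
        Fu[(size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k)] =
          -0.5 * (divf + advf) + invRe * dif + force[0];
      }
  // v faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int o = std::min(cellOrder(orderCell, g, i, j - 1, k),
                         cellOrder(orderCell, g, i, j, k));
        double va = V.at(i, j, k);
        double vcL = 0.5 * (V.at(i, j - 1, k) + va);
        double vcR = 0.5 * (va + V.at(i, j + 1, k));
        double uaL = 0.5 * (U.at(i, j - 1, k) + U.at(i, j, k));
        double uaR = 0.5 * (U.at(i + 1, j - 1, k) + U.at(i + 1, j, k));
        double vaL = 0.5 * (V.at(i - 1, j, k) + va);
        double vaR = 0.5 * (va + V.at(i + 1, j, k));
        double waL = 0.5 * (W.at(i, j - 1, k) + W.at(i, j, k));
        double waR = 0.5 * (W.at(i, j - 1, k + 1) + W.at(i, j, k + 1));
        double vaB = 0.5 * (V.at(i, j, k - 1) + va);
        double vaT = 0.5 * (va + V.at(i, j, k + 1));
        double divf = (uaR * vaR - uaL * vaL) / g.hx +
                      (vcR * vcR - vcL * vcL) / g.hy +
                      (waR * vaT - waL * vaB) / g.hz;
        double advf =
          0.5 * (uaL + uaR) * (V.at(i + 1, j, k) - V.at(i - 1, j, k)) / (2 * g.hx) +
          va * (V.at(i, j + 1, k) - V.at(i, j - 1, k)) / (2 * g.hy) +
          0.5 * (waL + waR) * (V.at(i, j, k + 1) - V.at(i, j, k - 1)) / (2 * g.hz);
        double dif = cderiv(V, i, j, k, 0, 2, o, g.hx) +
                     cderiv(V, i, j, k, 1, 2, o, g.hy) +
                     cderiv(V, i, j, k, 2, 2, o, g.hz);
        Fv[(size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k)] =
          -0.5 * (divf + advf) + invRe * dif + force[1];
      }
  // w faces
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int o = std::min(cellOrder(orderCell, g, i, j, k - 1),
                         cellOrder(orderCell, g, i, j, k));
        double wa = W.at(i, j, k);
        double wcB = 0.5 * (W.at(i, j, k - 1) + wa);
        double wcT = 0.5 * (wa + W.at(i, j, k + 1));
        double uaL = 0.5 * (U.at(i, j, k - 1) + U.at(i, j, k));
        double uaR = 0.5 * (U.at(i + 1, j, k - 1) + U.at(i + 1, j, k));
        double waL = 0.5 * (W.at(i - 1, j, k) + wa);
        double waR = 0.5 * (wa + W.at(i + 1, j, k));
        double vaL = 0.5 * (V.at(i, j, k - 1) + V.at(i, j, k));
        double vaR = 0.5 * (V.at(i, j + 1, k - 1) + V.at(i, j + 1, k));
        double waB = 0.5 * (W.at(i, j - 1, k) + wa);
        double waT = 0.5 * (wa + W.at(i, j + 1, k));
        double divf = (uaR * waR - uaL * waL) / g.hx +
                      (vaR * waT - vaL * waB) / g.hy +
                      (wcT * wcT - wcB * wcB) / g.hz;
        double advf =
          0.5 * (uaL + uaR) * (W.at(i + 1, j, k) - W.at(i - 1, j, k)) / (2 * g.hx) +
          0.5 * (vaL + vaR) * (W.at(i, j + 1, k) - W.at(i, j - 1, k)) / (2 * g.hy) +
          wa * (W.at(i, j, k + 1) - W.at(i, j, k - 1)) / (2 * g.hz);
        double dif = cderiv(W, i, j, k, 0, 2, o, g.hx) +
                     cderiv(W, i, j, k, 1, 2, o, g.hy) +
                     cderiv(W, i, j, k, 2, 2, o, g.hz);
        Fw[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] =
          -0.5 * (divf + advf) + invRe * dif + force[2];
      }
  return List::create(_["Fu"] = Fu, _["Fv"] = Fv, _["Fw"] = Fw);
}

// [[Rcpp::export]]
NumericVector divergence_cpp(NumericVector u, NumericVector v, NumericVector w,
                             IntegerVector dims, NumericVector h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector d((size_t)nx * ny * nz);
  const double *U = REAL(u), *V = REAL(v), *W = REAL(w);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        double du = U[(size_t)(i + 1) + (size_t)(nx + 1) * (j + (size_t)ny * k)] -
                    U[(size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k)];
        double dv = V[(size_t)i + (size_t)nx * ((j + 1) + (size_t)(ny + 1) * k)] -
                    V[(size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k)];
        double dw = W[(size_t)i + (size_t)nx * (j + (size_t)ny * (k + 1))] -
                    W[(size_t)i + (size_t)nx * (j + (size_t)ny * k)];
        d[c] = du / h[0] + dv / h[1] + dw / h[2];
      }
  return d;
}

// trilinear sample of one staggered component at physical point (px,py,pz)
static double sampleComp(const Comp& c, double px, double py, double pz) {
  const Grid& g = *c.g;
  double fx = px / g.hx - (c.s == 0 ? 0.0 : 0.5);
  double fy = py / g.hy - (c.s == 1 ? 0.0 : 0.5);
  double fz = pz / g.hz - (c.s == 2 ? 0.0 : 0.5);
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double ax = fx - i0, ay = fy - j0, az = fz - k0;
  double s = 0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double wgt = (di ? ax : 1 - ax) * (dj ? ay : 1 - ay) * (dk ? az : 1 - az);
        s += wgt * c.at(i0 + di, j0 + dj, k0 + dk);
      }
  return s;
}

// triquadratic (3-point Lagrange per axis) sample; third-order accurate
static double sampleComp2(const Comp& c, double px, double py, double pz) {
  const Grid& g = *c.g;
  double f[3] = {px / g.hx - (c.s == 0 ? 0.0 : 0.5),
                 py / g.hy - (c.s == 1 ? 0.0 : 0.5),
                 pz / g.hz - (c.s == 2 ? 0.0 : 0.5)};
  int base[3];
  double wq[3][3];
  for (int a = 0; a < 3; ++a) {
    int ic = (int)std::floor(f[a] + 0.5);  // nearest node
    double xi = f[a] - ic;                 // in [-0.5, 0.5]
    base[a] = ic;
    wq[a][0] = 0.5 * xi * (xi - 1.0);
    wq[a][1] = 1.0 - xi * xi;
    wq[a][2] = 0.5 * xi * (xi + 1.0);
  }
  double s = 0;
  for (int dk = 0; dk < 3; ++dk)
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        double wgt = wq[0][di] * wq[1][dj] * wq[2][dk];
        if (wgt != 0)
          s += wgt * c.at(base[0] + di - 1, base[1] + dj - 1,
                          base[2] + dk - 1);
      }
  return s;
}

// quadratic sample clamped to the range of the enclosing trilinear cell:
// keeps third-order accuracy on monotone data but cannot overshoot, which
// matters when reconstruction probes sit in ragged near-wall regions
static double sampleComp2clamped(const Comp& c, double px, double py,
                                 double pz) {
  double v = sampleComp2(c, px, py, pz);
  const Grid& g = *c.g;
  double fx = px / g.hx - (c.s == 0 ? 0.0 : 0.5);
  double fy = py / g.hy - (c.s == 1 ? 0.0 : 0.5);
  double fz = pz / g.hz - (c.s == 2 ? 0.0 : 0.5);
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  double lo = 1e300, hi = -1e300;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double q = c.at(i0 + di, j0 + dj, k0 + dk);
        lo = std::min(lo, q); hi = std::max(hi, q);
      }
  return std::min(std::max(v, lo), hi);
}

// [[Rcpp::export]]
NumericVector sample_comp_cpp(NumericVector a, IntegerVector adims, int stag,
                              IntegerVector dims, NumericVector h,
                              LogicalVector periodic, NumericMatrix pts,
                              int order = 1) {
  Grid g{dims[0], dims[1], dims[2], h[0], h[1], h[2],
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  Comp C{REAL(a), adims[0], adims[1], adims[2], stag, &g};
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q)
    out[q] = (order >= 2) ? sampleComp2(C, pts(q, 0), pts(q, 1), pts(q, 2))
                          : sampleComp(C, pts(q, 0), pts(q, 1), pts(q, 2));
  return out;
}

// Sharp-interface reconstruction of near-wall faces: face value = quadratic
// no-slip profile through the wall (zero) and two interpolated fluid probes
// along the local normal. idx: 0-based flat face indices; f1/f2: Lagrange
// coefficients of the two probes at the face's wall distance; pts1/pts2:
// probe locations. Probes are sampled from a snapshot so the pass is
// order-independent.
// [[Rcpp::export]]
NumericVector ibm_apply_cpp(NumericVector a, IntegerVector adims, int stag,
                            IntegerVector dims, NumericVector h,
                            LogicalVector periodic, IntegerVector idx,
                            NumericVector f1, NumericMatrix pts1,
                            NumericVector f2, NumericMatrix pts2,
                            double relax = 0.5) {
  Grid g{dims[0], dims[1], dims[2], h[0], h[1], h[2],
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  NumericVector snap = clone(a);
  Comp C{REAL(snap), adims[0], adims[1], adims[2], stag, &g};
  int n = idx.size();
  // under-relaxation damps the reconstruction<->projection cycle in
  // narrow (few-cell) tubes without moving its fixed point
  for (int q = 0; q < n; ++q) {
    double val =
      f1[q] * sampleComp2clamped(C, pts1(q, 0), pts1(q, 1), pts1(q, 2)) +
      f2[q] * sampleComp2clamped(C, pts2(q, 0), pts2(q, 1), pts2(q, 2));
    a[idx[q]] = relax * val + (1.0 - relax) * a[idx[q]];
  }
  return a;
}

// divergence with masked (wall/ghost) faces treated as impermeable
// [[Rcpp::export]]
NumericVector divergence_masked_cpp(NumericVector u, NumericVector v,
                                    NumericVector w, IntegerVector maskU,
                                    IntegerVector maskV, IntegerVector maskW,
                                    IntegerVector dims, NumericVector h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector d((size_t)nx * ny * nz);
  const double *U = REAL(u), *V = REAL(v), *W = REAL(w);
  const int *mU = INTEGER(maskU), *mV = INTEGER(maskV), *mW = INTEGER(maskW);
  auto fu = [&](int i, int j, int k) {
    size_t f = (size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k);
    return mU[f] ? 0.0 : U[f];
  };
  auto fv = [&](int i, int j, int k) {
    size_t f = (size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k);
    return mV[f] ? 0.0 : V[f];
  };
  auto fw = [&](int i, int j, int k) {
    size_t f = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
    return mW[f] ? 0.0 : W[f];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        d[c] = (fu(i + 1, j, k) - fu(i, j, k)) / h[0] +
               (fv(i, j + 1, k) - fv(i, j, k)) / h[1] +
               (fw(i, j, k + 1) - fw(i, j, k)) / h[2];
      }
  return d;
}

// ---------------------------------------------------------------------------
// Pressure Poisson: matrix-free 7-point Laplacian on the masked domain.
// ctype: 0 excluded (solid / prescribed-velocity fringe), 1 unknown,
//        2 Dirichlet (value in dirval). A link between two cells exists only
// if the shared face is free (fix* == 0) and both cells are not excluded.
// Solves  A p = b  (A = negative masked Laplacian, SPD once a Dirichlet cell
// exists; pure-Neumann systems are projected to mean zero).

struct PoissonCtx {
  const int* ctype;
  const double* dirval;
  const int *fixu, *fixv, *fixw;
  Grid g;
  inline size_t cidx(int i, int j, int k) const {
    return (size_t)i + (size_t)g.nx * (j + (size_t)g.ny * k);
  }
  inline bool link(int i, int j, int k, int axis, int dir,
                   size_t* nb, double* coef, bool* isDir) const {
    int ii = i, jj = j, kk = k;
    if (axis == 0) ii += dir; else if (axis == 1) jj += dir; else kk += dir;
    bool per = (axis == 0) ? g.px : (axis == 1) ? g.py : g.pz;
    int n = (axis == 0) ? g.nx : (axis == 1) ? g.ny : g.nz;
    int raw = (axis == 0) ? ii : (axis == 1) ? jj : kk;
    if (!per && (raw < 0 || raw >= n)) return false;
    ii = wrapc(ii, g.nx, g.px); jj = wrapc(jj, g.ny, g.py); kk = wrapc(kk, g.nz, g.pz);
    // face index between (i,j,k) and neighbour
    size_t f;
    if (axis == 0) {
      int fi = (dir > 0) ? i + 1 : i;
      if (g.px) fi = wrapc(fi, g.nx, true);
      f = (size_t)fi + (size_t)(g.nx + 1) * (j + (size_t)g.ny * k);
      if (fixu[f]) return false;
    } else if (axis == 1) {
      int fj = (dir > 0) ? j + 1 : j;
      if (g.py) fj = wrapc(fj, g.ny, true);
      f = (size_t)i + (size_t)g.nx * (fj + (size_t)(g.ny + 1) * k);
      if (fixv[f]) return false;
    } else {
      int fk = (dir > 0) ? k + 1 : k;
      if (g.pz) fk = wrapc(fk, g.nz, true);
      f = (size_t)i + (size_t)g.nx * (j + (size_t)g.ny * fk);
      if (fixw[f]) return false;
    }
    size_t nc = cidx(ii, jj, kk);
    if (ctype[nc] == 0) return false;
    *nb = nc;
    double hh = (axis == 0) ? g.hx : (axis == 1) ? g.hy : g.hz;
    *coef = 1.0 / (hh * hh);
    *isDir = (ctype[nc] == 2);
    return true;
  }
};

// [[Rcpp::export]]
List poisson_cg_cpp(NumericVector rhs, IntegerVector ctype, NumericVector dirval,
                    IntegerVector fixu, IntegerVector fixv, IntegerVector fixw,
                    IntegerVector dims, NumericVector h, LogicalVector periodic,
                    NumericVector pinit, double tol, int maxit) {
  Grid g{dims[0], dims[1], dims[2], h[0], h[1], h[2],
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  PoissonCtx P{INTEGER(ctype), REAL(dirval), INTEGER(fixu), INTEGER(fixv),
               INTEGER(fixw), g};
  int nx = g.nx, ny = g.ny, nz = g.nz;
  size_t N = (size_t)nx * ny * nz;
  std::vector<size_t> cells;
  std::vector<int> compact(N, -1);
  bool anyDir = false;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = P.cidx(i, j, k);
        if (ctype[c] == 1) { compact[c] = (int)cells.size(); cells.push_back(c); }
        if (ctype[c] == 2) anyDir = true;
      }
  size_t n = cells.size();
  if (n == 0)
    return List::create(_["p"] = pinit, _["iter"] = 0, _["resid"] = 0.0,
                        _["projected"] = false);

  // compact CSR structure of the masked 7-point operator
  std::vector<int> ptr(n + 1, 0), cols;
  std::vector<double> vals, diag(n), b(n);
  cols.reserve(6 * n); vals.reserve(6 * n);
  for (size_t q = 0; q < n; ++q) {
    size_t c = cells[q];
    int i = c % nx, j = (c / nx) % ny, k = c / ((size_t)nx * ny);
    double bb = -rhs[c], dg = 0;
    for (int axis = 0; axis < 3; ++axis)
      for (int dir = -1; dir <= 1; dir += 2) {
        size_t nb; double cf; bool isDir;
        if (P.link(i, j, k, axis, dir, &nb, &cf, &isDir)) {
          dg += cf;
          if (isDir) bb += cf * dirval[nb];
          else { cols.push_back(compact[nb]); vals.push_back(-cf); }
        }
      }
    ptr[q + 1] = (int)cols.size();
    diag[q] = (dg > 0) ? dg : 1.0;
    b[q] = bb;
  }

  bool projected = false;
  if (!anyDir) {
    double mb = 0, maxb = 0;
    for (size_t q = 0; q < n; ++q) {
      mb += b[q];
      maxb = std::max(maxb, std::abs(b[q]));
    }
    mb /= n;
    // flag only genuine incompatibility, not round-off in the mean
    if (std::abs(mb) > 1e-10 * (maxb + 1.0)) projected = true;
    for (size_t q = 0; q < n; ++q) b[q] -= mb;
  }

  auto applyA = [&](const double* x, double* y) {
    for (size_t q = 0; q < n; ++q) {
      double s = diag[q] * x[q];
      for (int m = ptr[q]; m < ptr[q + 1]; ++m) s += vals[m] * x[cols[m]];
      y[q] = s;
    }
  };
  // SSOR (symmetric Gauss-Seidel) preconditioner: z = M^{-1} r
  std::vector<double> yv(n);
  auto applyM = [&](const double* r, double* z) {
    for (size_t q = 0; q < n; ++q) {
      double s = r[q];
      for (int m = ptr[q]; m < ptr[q + 1]; ++m)
        if ((size_t)cols[m] < q) s -= vals[m] * yv[cols[m]];
      yv[q] = s / diag[q];
    }
    for (size_t q = 0; q < n; ++q) yv[q] *= diag[q];
    for (size_t qq = n; qq-- > 0;) {
      double s = yv[qq];
      for (int m = ptr[qq]; m < ptr[qq + 1]; ++m)
        if ((size_t)cols[m] > qq) s -= vals[m] * z[cols[m]];
      z[qq] = s / diag[qq];
    }
  };

  std::vector<double> x(n), r(n), z(n), d(n), Ad(n);
  for (size_t q = 0; q < n; ++q) x[q] = pinit[cells[q]];
  applyA(x.data(), Ad.data());
  double rinf = 0;
  for (size_t q = 0; q < n; ++q) {
    r[q] = b[q] - Ad[q];
    rinf = std::max(rinf, std::abs(r[q]));
  }
  applyM(r.data(), z.data());
  double rz = 0;
  for (size_t q = 0; q < n; ++q) { d[q] = z[q]; rz += r[q] * z[q]; }
  int it = 0;
  while (rinf > tol && it < maxit) {
    applyA(d.data(), Ad.data());
    double dAd = 0;
    for (size_t q = 0; q < n; ++q) dAd += d[q] * Ad[q];
    if (dAd <= 0) break;
    double alpha = rz / dAd;
    rinf = 0;
    for (size_t q = 0; q < n; ++q) {
      x[q] += alpha * d[q];
      r[q] -= alpha * Ad[q];
      rinf = std::max(rinf, std::abs(r[q]));
    }
    if (rinf <= tol) { ++it; break; }
    applyM(r.data(), z.data());
    double rz2 = 0;
    for (size_t q = 0; q < n; ++q) rz2 += r[q] * z[q];
    double beta = rz2 / rz;
    rz = rz2;
    for (size_t q = 0; q < n; ++q) d[q] = z[q] + beta * d[q];
    ++it;
  }
  if (!anyDir) {
    double mx = 0; for (size_t q = 0; q < n; ++q) mx += x[q];
    mx /= n;
    for (size_t q = 0; q < n; ++q) x[q] -= mx;
  }
  NumericVector p(N);
  for (size_t c = 0; c < N; ++c) {
    p[c] = (ctype[c] == 2) ? dirval[c]
         : (compact[c] >= 0 ? x[compact[c]] : 0.0);
  }
  return List::create(_["p"] = p, _["iter"] = it, _["resid"] = rinf,
                      _["projected"] = projected);
}

// subtract scale * grad(p) from free faces whose two cells are both active
// [[Rcpp::export]]
void grad_correct_cpp(NumericVector u, NumericVector v, NumericVector w,
                      NumericVector p, IntegerVector ctype,
                      IntegerVector fixu, IntegerVector fixv, IntegerVector fixw,
                      IntegerVector dims, NumericVector h,
                      LogicalVector periodic, double scale) {
  Grid g{dims[0], dims[1], dims[2], h[0], h[1], h[2],
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  int nx = g.nx, ny = g.ny, nz = g.nz;
  const int* ct = INTEGER(ctype);
  const double* pp = REAL(p);
  auto cidx = [&](int i, int j, int k) {
    i = wrapc(i, nx, g.px); j = wrapc(j, ny, g.py); k = wrapc(k, nz, g.pz);
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  // u faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        if (!g.px && (i == 0 || i == nx)) continue;
        size_t f = (size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k);
        if (fixu[f]) continue;
        size_t cL = cidx(i - 1, j, k), cR = cidx(i, j, k);
        if (ct[cL] == 0 || ct[cR] == 0) continue;
        u[f] -= scale * (pp[cR] - pp[cL]) / g.hx;
      }
  // v faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!g.py && (j == 0 || j == ny)) continue;
        size_t f = (size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k);
        if (fixv[f]) continue;
        size_t cL = cidx(i, j - 1, k), cR = cidx(i, j, k);
        if (ct[cL] == 0 || ct[cR] == 0) continue;
        v[f] -= scale * (pp[cR] - pp[cL]) / g.hy;
      }
  // w faces
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!g.pz && (k == 0 || k == nz)) continue;
        size_t f = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        if (fixw[f]) continue;
        size_t cL = cidx(i, j, k - 1), cR = cidx(i, j, k);
        if (ct[cL] == 0 || ct[cR] == 0) continue;
        w[f] -= scale * (pp[cR] - pp[cL]) / g.hz;
      }
}

// sixth-difference low-pass filter along each axis:
// u <- u + (amp/64) * delta^6 u ; removes near-Nyquist content (Nyquist
// mode damped by factor 1-amp), exact on polynomials up to degree 5.
// [[Rcpp::export]]
NumericVector filter6_cpp(NumericVector a, IntegerVector adims,
                          LogicalVector periodic, IntegerVector period,
                          double amp) {
  int n0 = adims[0], n1 = adims[1], n2 = adims[2];
  static const double C6[7] = {1, -6, 15, -20, 15, -6, 1};
  NumericVector out = clone(a);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)n0 * (j + (size_t)n1 * k);
  };
  for (int axis = 0; axis < 3; ++axis) {
    int n = adims[axis];
    if (n < 8) continue;
    bool per = periodic[axis];
    int m = period[axis];  // logical period (cell count) for staggered axes
    NumericVector src = clone(out);
    for (int k = 0; k < n2; ++k)
      for (int j = 0; j < n1; ++j)
        for (int i = 0; i < n0; ++i) {
          double s = 0;
          for (int q = -3; q <= 3; ++q) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii += q; else if (axis == 1) jj += q; else kk += q;
            int* t = (axis == 0) ? &ii : (axis == 1) ? &jj : &kk;
            if (per) { *t %= m; if (*t < 0) *t += m; }
            else { *t = std::min(std::max(*t, 0), n - 1); }
            s += C6[q + 3] * src[idx(ii, jj, kk)];
          }
          out[idx(i, j, k)] += amp / 64.0 * s;
        }
  }
  return out;
}

// interior-depth map: 0 on non-fluid cells, else min cell distance to a
// non-fluid cell (chamfer, capped)
// [[Rcpp::export]]
IntegerVector interior_depth_cpp(IntegerVector fluid, IntegerVector dims,
                                 LogicalVector periodic, int cap) {
  Grid g{dims[0], dims[1], dims[2], 1, 1, 1,
         (bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  int nx = g.nx, ny = g.ny, nz = g.nz;
  size_t N = (size_t)nx * ny * nz;
  IntegerVector d(N);
  for (size_t c = 0; c < N; ++c) d[c] = fluid[c] ? cap : 0;
  auto cidx = [&](int i, int j, int k) {
    i = wrapc(i, nx, g.px); j = wrapc(j, ny, g.py); k = wrapc(k, nz, g.pz);
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  for (int pass = 0; pass < cap; ++pass) {
    bool changed = false;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = cidx(i, j, k);
          if (!fluid[c]) continue;
          int m = d[c];
          const int di[6] = {-1, 1, 0, 0, 0, 0};
          const int dj[6] = {0, 0, -1, 1, 0, 0};
          const int dk[6] = {0, 0, 0, 0, -1, 1};
          for (int q = 0; q < 6; ++q) {
            // non-periodic domain edges count as interior (clamped)
            int nb = d[cidx(i + di[q], j + dj[q], k + dk[q])];
            if (nb + 1 < m) m = nb + 1;
          }
          if (m != d[c]) { d[c] = m; changed = true; }
        }
    if (!changed) break;
  }
  return d;
}
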