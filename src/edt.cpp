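#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform of a
// sampled function f on a grid with spacing h (lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < h * q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// squared Euclidean distance transform to the set {seed != 0}, anisotropic
static std::vector<double> edt3(const IntegerVector& seed,
                                int nx, int ny, int nz,
                                double hx, double hy, double hz) {
  const double INF = 1e30;
  size_t N = (size_t)nx * ny * nz;
  std::vector<double> D(N);
  for (size_t i = 0; i < N; ++i) D[i] = seed[i] != 0 ? 0.0 : INF;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = D[idx(i, j, k)];
        dt1d(f, d, hx, nx);
        for (int i = 0; i < nx; ++i) D[idx(i, j, k)] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = D[idx(i, j, k)];
        dt1d(f, d, hy, ny);
        for (int j = 0; j < ny; ++j) D[idx(i, j, k)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = D[idx(i, j, k)];
        dt1d(f, d, hz, nz);
        for (int k = 0; k < nz; ++k) D[idx(i, j, k)] = d[k];
      }
  }
  return D;
}

// [[Rcpp::export]]
NumericVector edt_signed_cpp(IntegerVector fluid, IntegerVector dims,
                             NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector solid(N);
  for (size_t i = 0; i < N; ++i) solid[i] = fluid[i] ? 0 : 1;
  std::vector<double> dFluid = edt3(fluid, nx, ny, nz,
                                    spacing[0], spacing[1], spacing[2]);
  std::vector<double> dSolid = edt3(solid, nx, ny, nz,
                                    spacing[0], spacing[1], spacing[2]);
  NumericVector phi(N);
  // negative inside fluid: distance-to-fluid minus distance-to-solid
  for (size_t i = 0; i < N; ++i)
    phi[i] = std::sqrt(dFluid[i]) - std::sqrt(dSolid[i]);
  return phi;
}

// [[Rcpp::export]]
IntegerVector largest_component_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<int> lab(N, 0);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  int next = 0, best = 0;
  size_t bestSize = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    size_t size = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      ++size;
      int i = c % nx, j = (c / nx) % ny, k = c / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t nb = idx(ii, jj, kk);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
      }
    }
    if (size > bestSize) { bestSize = size; best = next; }
  }
  IntegerVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = lab[i] == best ? 1 : 0;
  return out;
}

// tags: 0 solid, 1 fluid, 2 boundary (fluid with a solid face-neighbour).
// Out-of-domain neighbours are clamped (replicated), so a fluid column that
// reaches the domain face is not spuriously tagged as boundary there.
// [[Rcpp::export]]
IntegerVector classify_cells_cpp(NumericVector phi, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector tags(N);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t c = idx(i, j, k);
        if (phi[c] >= 0) { tags[c] = 0; continue; }
        bool bnd = false;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int m = 0; m < 6 && !bnd; ++m) {
          int ii = std::min(std::max(i + di[m], 0), nx - 1);
          int jj = std::min(std::max(j + dj[m], 0), ny - 1);
          int kk = std::min(std::max(k + dk[m], 0), nz - 1);
          if (phi[idx(ii, jj, kk)] >= 0) bnd = true;
        }
        tags[c] = bnd ? 2 : 1;
      }
  return tags;
}
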