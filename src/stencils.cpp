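#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// central-difference coefficients, first and second derivative, order 2/4/6
static const double D1_2[3] = {-0.5, 0.0, 0.5};
static const double D1_4[5] = {1.0 / 12, -2.0 / 3, 0.0, 2.0 / 3, -1.0 / 12};
static const double D1_6[7] = {-1.0 / 60, 3.0 / 20, -3.0 / 4, 0.0,
                               3.0 / 4, -3.0 / 20, 1.0 / 60};
static const double D2_2[3] = {1.0, -2.0, 1.0};
static const double D2_4[5] = {-1.0 / 12, 4.0 / 3, -5.0 / 2, 4.0 / 3, -1.0 / 12};
static const double D2_6[7] = {1.0 / 90, -3.0 / 20, 3.0 / 2, -49.0 / 18,
                               3.0 / 2, -3.0 / 20, 1.0 / 90};

static const double* coefs(int deriv, int order, int* half) {
  if (deriv == 1) {
    if (order == 2) { *half = 1; return D1_2; }
    if (order == 4) { *half = 2; return D1_4; }
    *half = 3; return D1_6;
  }
  if (order == 2) { *half = 1; return D2_2; }
  if (order == 4) { *half = 2; return D2_4; }
  *half = 3; return D2_6;
}

// derivative of one line f[0..n-1]; near non-periodic ends the stencil
// degrades gracefully: widest centred stencil that fits, one-sided 2nd
// order at the very ends.
static void line_deriv(const double* f, double* g, int n, double h,
                       int deriv, int order, bool periodic) {
  int half;
  const double* c = coefs(deriv, order, &half);
  double scale = (deriv == 1) ? 1.0 / h : 1.0 / (h * h);
  for (int i = 0; i < n; ++i) {
    if (periodic) {
      double s = 0.0;
      for (int m = -half; m <= half; ++m) {
        int ii = (i + m) % n;
        if (ii < 0) ii += n;
        s += c[m + half] * f[ii];
      }
      g[i] = s * scale;
      continue;
    }
    int room = std::min(i, n - 1 - i);
    int use = std::min(half, room);
    if (use >= 1) {
      int uhalf;
      const double* uc = coefs(deriv, 2 * use, &uhalf);
      double s = 0.0;
      for (int m = -use; m <= use; ++m) s += uc[m + use] * f[i + m];
      g[i] = s * scale;
    } else if (deriv == 1) {
      g[i] = (i == 0) ? (-1.5 * f[0] + 2.0 * f[1] - 0.5 * f[2]) / h
                      : (1.5 * f[n - 1] - 2.0 * f[n - 2] + 0.5 * f[n - 3]) / h;
    } else {
      g[i] = (i == 0)
        ? (2.0 * f[0] - 5.0 * f[1] + 4.0 * f[2] - f[3]) / (h * h)
        : (2.0 * f[n - 1] - 5.0 * f[n - 2] + 4.0 * f[n - 3] - f[n - 4]) / (h * h);
    }
  }
}

// [[Rcpp::export]]
NumericVector fd_apply_cpp(NumericVector field, IntegerVector dims,
                           int axis, int deriv, int order, double h,
                           bool periodic) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  int n = dims[axis];
  std::vector<double> f(n), g(n);
  size_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  // iterate over all lines along `axis`
  int nlines = N / n;
  for (int l = 0; l < nlines; ++l) {
    // decompose l into the two non-axis indices to find the line start
    size_t start;
    if (axis == 0) {
      start = (size_t)l * nx;
    } else if (axis == 1) {
      int i = l % nx, k = l / nx;
      start = (size_t)i + (size_t)nx * ny * k;
    } else {
      start = (size_t)l;
    }
    for (int q = 0; q < n; ++q) f[q] = field[start + stride * q];
    line_deriv(f.data(), g.data(), n, h, deriv, order, periodic);
    for (int q = 0; q < n; ++q) out[start + stride * q] = g[q];
  }
  return out;
}
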