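// Smoothed isotropic total variation and its gradient with periodic
// boundaries, matching the R-level grad_vol/gradT_vol convention:
// TV_delta(x) = sum_j sqrt(|forward_diff(x)_j|^2 + delta^2).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline int wrap_next(int i, int n) { return (i + 1 < n) ? i + 1 : 0; }

// [[Rcpp::export]]
double cpp_smoothed_tv(NumericVector x, IntegerVector dims, double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = x.begin();
  const double d2 = delta * delta;
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  double acc = 0.0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t o = i * sx + j * sy + k * sz;
        const double c = v[o];
        const double gx = v[wrap_next(i, nx) * sx + j * sy + k * sz] - c;
        const double gy = v[i * sx + wrap_next(j, ny) * sy + k * sz] - c;
        const double gz = v[i * sx + j * sy + wrap_next(k, nz) * sz] - c;
        acc += std::sqrt(gx * gx + gy * gy + gz * gz + d2);
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_smoothed_tv_grad(NumericVector x, IntegerVector dims,
                                   double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = x.begin();
  const double d2 = delta * delta;
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  NumericVector out(x.size());
  double* g = out.begin();
  // normalized forward differences, then the adjoint difference (grad^T)
  std::vector<double> wx(x.size()), wy(x.size()), wz(x.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t o = i * sx + j * sy + k * sz;
        const double c = v[o];
        const double gx = v[wrap_next(i, nx) * sx + j * sy + k * sz] - c;
        const double gy = v[i * sx + wrap_next(j, ny) * sy + k * sz] - c;
        const double gz = v[i * sx + j * sy + wrap_next(k, nz) * sz] - c;
        const double w = std::sqrt(gx * gx + gy * gy + gz * gz + d2);
        wx[o] = gx / w; wy[o] = gy / w; wz[o] = gz / w;
      }
    }
  }
  for (int k = 0; k < nz; ++k) {
    const int km = (k > 0) ? k - 1 : nz - 1;
    for (int j = 0; j < ny; ++j) {
      const int jm = (j > 0) ? j - 1 : ny - 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i > 0) ? i - 1 : nx - 1;
        const R_xlen_t o = i * sx + j * sy + k * sz;
        g[o] = (wx[im * sx + j * sy + k * sz] - wx[o]) +
               (wy[i * sx + jm * sy + k * sz] - wy[o]) +
               (wz[i * sx + j * sy + km * sz] - wz[o]);
      }
    }
  }
  return out;
}
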