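// Matrix-free Siddon ray traversal for circular cone-beam geometries.
//
// All functions operate per view: the caller supplies the source position,
// the world position of the centre of detector pixel (row 0, col 0) and the
// per-row / per-column step vectors.  Volumes are column-major (nx, ny, nz)
// arrays; world x runs along dim 1.  A and A^T share one traversal routine,
// so the pair is adjoint by construction.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

struct GridSpec {
  int n[3];       // voxels per axis
  double sp[3];   // voxel size, mm
  double lo[3];   // min corner, mm
  double hi[3];
};

GridSpec make_grid(const IntegerVector& dims, const NumericVector& vox,
                   const NumericVector& corner) {
  if (dims.size() != 3 || vox.size() != 3 || corner.size() != 3)
    stop("grid spec must have 3 components per field");
  GridSpec g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dims[a];
    g.sp[a] = vox[a];
    g.lo[a] = corner[a];
    g.hi[a] = corner[a] + dims[a] * vox[a];
    if (g.n[a] < 1) stop("grid shape entries must be >= 1");
    if (g.sp[a] <= 0) stop("voxel sizes must be > 0");
  }
  return g;
}

// Walk the segment s -> d through g, calling fn(ix, iy, iz, chord_mm) for
// every voxel crossed.  Segment lengths telescope exactly over [tmin, tmax].
template <typename F>
void traverse(const GridSpec& g, const double* s, const double* d, F&& fn) {
  double w[3], L2 = 0.0;
  for (int a = 0; a < 3; ++a) { w[a] = d[a] - s[a]; L2 += w[a] * w[a]; }
  const double L = std::sqrt(L2);
  if (L == 0.0) return;

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (w[a] == 0.0) {
      if (s[a] <= g.lo[a] || s[a] >= g.hi[a]) return;
    } else {
      double t1 = (g.lo[a] - s[a]) / w[a];
      double t2 = (g.hi[a] - s[a]) / w[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin >= tmax) return;

  const double inf = std::numeric_limits<double>::infinity();
  int idx[3], step[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    double p = s[a] + w[a] * tmin;
    int i = static_cast<int>(std::floor((p - g.lo[a]) / g.sp[a]));
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
    if (w[a] > 0.0) {
      step[a] = 1;
      tMax[a] = ((g.lo[a] + (i + 1) * g.sp[a]) - s[a]) / w[a];
      tDelta[a] = g.sp[a] / w[a];
    } else if (w[a] < 0.0) {
      step[a] = -1;
      tMax[a] = ((g.lo[a] + i * g.sp[a]) - s[a]) / w[a];
      tDelta[a] = -g.sp[a] / w[a];
    } else {
      step[a] = 0;
      tMax[a] = inf;
      tDelta[a] = inf;
    }
    // entry plane itself can give tMax == tmin; nudge past it
    while (tMax[a] <= tmin) tMax[a] += tDelta[a];
  }

  double t = tmin;
  for (;;) {
    double tnext = tmax;
    bool boundary = true;
    for (int a = 0; a < 3; ++a)
      if (tMax[a] < tnext) { tnext = tMax[a]; boundary = false; }
    double len = (tnext - t) * L;
    if (len > 0.0) fn(idx[0], idx[1], idx[2], len);
    if (boundary) break;
    for (int a = 0; a < 3; ++a) {
      if (tMax[a] <= tnext) {
        idx[a] += step[a];
        if (idx[a] < 0 || idx[a] >= g.n[a]) return;
        tMax[a] += tDelta[a];
      }
    }
    t = tnext;
  }
}

inline void pixel_pos(const double* det00, const double* eu, const double* ev,
                      int r, int c, double* out) {
  for (int a = 0; a < 3; ++a) out[a] = det00[a] + r * ev[a] + c * eu[a];
}

}  // namespace

// Forward projection of one view: frame[r, c] = sum_j a_ij x_j.
// [[Rcpp::export]]
NumericMatrix cpp_forward_view(NumericVector vol, IntegerVector dims,
                               NumericVector vox, NumericVector corner,
                               NumericVector src, NumericVector det00,
                               NumericVector eu, NumericVector ev,
                               int nrow, int ncol) {
  GridSpec g = make_grid(dims, vox, corner);
  const double* x = vol.begin();
  const int nx = g.n[0], nxy = g.n[0] * g.n[1];
  NumericMatrix frame(nrow, ncol);
  double d[3];
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      pixel_pos(det00.begin(), eu.begin(), ev.begin(), r, c, d);
      double acc = 0.0;
      traverse(g, src.begin(), d, [&](int ix, int iy, int iz, double len) {
        acc += len * x[ix + nx * iy + nxy * iz];
      });
      frame(r, c) = acc;
    }
  }
  return frame;
}

// Back projection of one view: vol_j += sum_{i in view} a_ij y_i.
// [[Rcpp::export]]
NumericVector cpp_back_view(NumericMatrix frame, IntegerVector dims,
                            NumericVector vox, NumericVector corner,
                            NumericVector src, NumericVector det00,
                            NumericVector eu, NumericVector ev) {
  GridSpec g = make_grid(dims, vox, corner);
  const int nx = g.n[0], nxy = g.n[0] * g.n[1];
  NumericVector vol(static_cast<R_xlen_t>(g.n[0]) * g.n[1] * g.n[2]);
  double* out = vol.begin();
  double d[3];
  for (int c = 0; c < frame.ncol(); ++c) {
    for (int r = 0; r < frame.nrow(); ++r) {
      const double y = frame(r, c);
      if (y == 0.0) continue;
      pixel_pos(det00.begin(), eu.begin(), ev.begin(), r, c, d);
      traverse(g, src.begin(), d, [&](int ix, int iy, int iz, double len) {
        out[ix + nx * iy + nxy * iz] += len * y;
      });
    }
  }
  return vol;
}

// Per-ray intersection length totals for one view (row sums of A restricted
// to the view): frame[r, c] = sum_j a_ij.
// [[Rcpp::export]]
NumericMatrix cpp_ray_sums_view(IntegerVector dims, NumericVector vox,
                                NumericVector corner, NumericVector src,
                                NumericVector det00, NumericVector eu,
                                NumericVector ev, int nrow, int ncol) {
  GridSpec g = make_grid(dims, vox, corner);
  NumericMatrix frame(nrow, ncol);
  double d[3];
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      pixel_pos(det00.begin(), eu.begin(), ev.begin(), r, c, d);
      double acc = 0.0;
      traverse(g, src.begin(), d, [&](int, int, int, double len) { acc += len; });
      frame(r, c) = acc;
    }
  }
  return frame;
}

// Per-voxel column sums of A restricted to one view: vol_j = sum_i a_ij.
// [[Rcpp::export]]
NumericVector cpp_voxel_sums_view(IntegerVector dims, NumericVector vox,
                                  NumericVector corner, NumericVector src,
                                  NumericVector det00, NumericVector eu,
                                  NumericVector ev, int nrow, int ncol) {
  GridSpec g = make_grid(dims, vox, corner);
  const int nx = g.n[0], nxy = g.n[0] * g.n[1];
  NumericVector vol(static_cast<R_xlen_t>(g.n[0]) * g.n[1] * g.n[2]);
  double* out = vol.begin();
  double d[3];
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      pixel_pos(det00.begin(), eu.begin(), ev.begin(), r, c, d);
      traverse(g, src.begin(), d, [&](int ix, int iy, int iz, double len) {
        out[ix + nx * iy + nxy * iz] += len;
      });
    }
  }
  return vol;
}

// Single-ray traversal: 1-based flat voxel indices plus chord lengths (mm).
// [[Rcpp::export]]
List cpp_trace_ray(IntegerVector dims, NumericVector vox, NumericVector corner,
                   NumericVector src, NumericVector det00, NumericVector eu,
                   NumericVector ev, int row, int col) {
  GridSpec g = make_grid(dims, vox, corner);
  const int nx = g.n[0], nxy = g.n[0] * g.n[1];
  double d[3];
  pixel_pos(det00.begin(), eu.begin(), ev.begin(), row, col, d);
  std::vector<int> js;
  std::vector<double> lens;
  traverse(g, src.begin(), d, [&](int ix, int iy, int iz, double len) {
    js.push_back(ix + nx * iy + nxy * iz + 1);
    lens.push_back(len);
  });
  return List::create(_["voxel_indices"] = wrap(js), _["lengths"] = wrap(lens));
}
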