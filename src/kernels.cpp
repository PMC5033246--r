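// Low-level array kernels: interpolation, separable convolution, distance
// transform, 6-connected labelling, and cubic B-spline free-form deformation.
// All arrays are column-major with dim = (nx, ny, nz), as in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  // Interpolating cubic (Catmull-Rom) between p1 and p2, t in [0,1]
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline double getv(const double* s, int nx, int ny, int nz,
                          int i, int j, int k, double fill) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return s[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Sample a 3D volume at continuous 0-based voxel coordinates.
// method: 0 nearest, 1 trilinear, 3 cubic (Catmull-Rom).
// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector src, IntegerVector sdim,
                         NumericVector xi, NumericVector yi, NumericVector zi,
                         int method, double fill) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const double* s = src.begin();
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    const double x = xi[v], y = yi[v], z = zi[v];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[v] = fill; continue; }
    if (method == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      out[v] = getv(s, nx, ny, nz, i, j, k, fill);
    } else if (method == 1) {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      if (i0 < -1 || j0 < -1 || k0 < -1 || i0 > nx - 1 || j0 > ny - 1 || k0 > nz - 1) {
        out[v] = fill; continue;
      }
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
            if (w > 0) acc += w * getv(s, nx, ny, nz, i0 + di, j0 + dj, k0 + dk, fill);
          }
      out[v] = acc;
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      double fx = x - i0, fy = y - j0, fz = z - k0;
      if (i0 < -2 || j0 < -2 || k0 < -2 || i0 > nx || j0 > ny || k0 > nz) {
        out[v] = fill; continue;
      }
      double plane[4];
      for (int dk = -1; dk <= 2; ++dk) {
        double row[4];
        for (int dj = -1; dj <= 2; ++dj) {
          double c0 = getv(s, nx, ny, nz, i0 - 1, j0 + dj, k0 + dk, fill);
          double c1 = getv(s, nx, ny, nz, i0,     j0 + dj, k0 + dk, fill);
          double c2 = getv(s, nx, ny, nz, i0 + 1, j0 + dj, k0 + dk, fill);
          double c3 = getv(s, nx, ny, nz, i0 + 2, j0 + dj, k0 + dk, fill);
          row[dj + 1] = catmull_rom(c0, c1, c2, c3, fx);
        }
        plane[dk + 1] = catmull_rom(row[0], row[1], row[2], row[3], fy);
      }
      out[v] = catmull_rom(plane[0], plane[1], plane[2], plane[3], fz);
    }
  }
  return out;
}

// 1D convolution along one axis of a 3D array with mirror (reflect) padding.
// axis: 0, 1 or 2. Kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv1(NumericVector src, IntegerVector dim,
                        NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), hw = kl / 2;
  NumericVector out(src.size());
  const double* s = src.begin();
  const double* k = kernel.begin();
  double* o = out.begin();
  const int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  // strides
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const size_t sa = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  // iterate over all lines along the axis
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  const size_t st1 = (axis == 0) ? sy : sx;
  const size_t st2 = (axis == 2) ? sy : sz;
  std::vector<double> line(nax);
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      const size_t base = a * st1 + b * st2;
      for (int t = 0; t < nax; ++t) line[t] = s[base + (size_t)t * sa];
      for (int t = 0; t < nax; ++t) {
        double acc = 0.0;
        for (int q = -hw; q <= hw; ++q) {
          int idx = t + q;
          // mirror padding (reflect about edge voxel centres)
          if (nax == 1) idx = 0;
          else {
            while (idx < 0 || idx >= nax) {
              if (idx < 0) idx = -idx;
              if (idx >= nax) idx = 2 * (nax - 1) - idx;
            }
          }
          acc += k[q + hw] * line[idx];
        }
        o[base + (size_t)t * sa] = acc;
      }
    }
  }
  return out;
}

// Box (moving-average) filter of half-width r along one axis with mirror
// padding; three passes approximate a Gaussian in O(n) regardless of sigma.
// [[Rcpp::export]]
NumericVector cpp_box1(NumericVector src, IntegerVector dim, int r,
                       int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(src.size());
  const double* s = src.begin();
  double* o = out.begin();
  const int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const size_t sa = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  const size_t st1 = (axis == 0) ? sy : sx;
  const size_t st2 = (axis == 2) ? sy : sz;
  const double w = 1.0 / (2 * r + 1);
  std::vector<double> line(nax);
  auto mirror = [&](int idx) {
    if (nax == 1) return 0;
    while (idx < 0 || idx >= nax) {
      if (idx < 0) idx = -idx;
      if (idx >= nax) idx = 2 * (nax - 1) - idx;
    }
    return idx;
  };
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      const size_t base = a * st1 + b * st2;
      for (int t = 0; t < nax; ++t) line[t] = s[base + (size_t)t * sa];
      double acc = 0.0;
      for (int q = -r; q <= r; ++q) acc += line[mirror(q)];
      o[base] = acc * w;
      for (int t = 1; t < nax; ++t) {
        acc += line[mirror(t + r)] - line[mirror(t - r - 1)];
        o[base + (size_t)t * sa] = acc * w;
      }
    }
  return out;
}

// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of each voxel to the nearest TRUE voxel, in voxel units
// scaled by per-axis spacing. Returns +Inf where mask has no TRUE.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n,
                  double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double sq = f[q] + s2 * q * q;
    double s;
    while (true) {
      s = (sq - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s2 * (q - v[k]) * (q - v[k]) + f[v[k]];
    d[q] = dq;
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = out.begin();
  // large finite stand-in for +infinity keeps the envelope
  // intersections finite (no inf - inf)
  const double BIG = 1e20;
  for (size_t t = 0; t < (size_t)out.size(); ++t)
    o[t] = mask[t] ? 0.0 : BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = o[base + i];
      edt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) o[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = o[base + (size_t)nx * j];
      edt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) o[base + (size_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = o[base + (size_t)nx * ny * k];
      edt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) o[base + (size_t)nx * ny * k] = d[k];
    }
  return out;
}

// 6-connected component labelling; labels start at 1 in scan order
// (relabelling by size happens in R).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<size_t> stack;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (size_t t = 0; t < n; ++t) {
    if (!mask[t] || lab[t]) continue;
    ++next;
    stack.push_back(t);
    lab[t] = next;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int i = (int)(c % nx);
      int j = (int)((c / nx) % ny);
      int k = (int)(c / ((size_t)nx * ny));
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t cc = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[cc] && !lab[cc]) { lab[cc] = next; stack.push_back(cc); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Cubic B-spline basis values for parameter t in [0,1)
static inline void bspline_w(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Evaluate a cubic B-spline free-form deformation given a control-point
// lattice. cp has dim (ncx, ncy, ncz, 3); control point (a,b,c) sits at
// voxel coordinate ((a-1) * spacing) so index 1 is at voxel 0 with one
// ring of points before the volume. Returns (nx*ny*nz*3) displacements
// in voxel units.
// [[Rcpp::export]]
NumericVector cpp_ffd_disp(NumericVector cp, IntegerVector cpdim,
                           IntegerVector odim, double spacing) {
  const int ncx = cpdim[0], ncy = cpdim[1], ncz = cpdim[2];
  const int nx = odim[0], ny = odim[1], nz = odim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const size_t ncp = (size_t)ncx * ncy * ncz;
  NumericVector out(nvox * 3);
  const double* c = cp.begin();
  double* o = out.begin();
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < nz; ++k) {
    double gz = (double)k / spacing;
    int bz = (int)std::floor(gz); double tz = gz - bz;
    bspline_w(tz, wz);
    for (int j = 0; j < ny; ++j) {
      double gy = (double)j / spacing;
      int by = (int)std::floor(gy); double ty = gy - by;
      bspline_w(ty, wy);
      for (int i = 0; i < nx; ++i) {
        double gx = (double)i / spacing;
        int bx = (int)std::floor(gx); double tx = gx - bx;
        bspline_w(tx, wx);
        double acc[3] = {0, 0, 0};
        for (int dz = 0; dz < 4; ++dz) {
          int cz = bz + dz; if (cz >= ncz) cz = ncz - 1;
          for (int dy = 0; dy < 4; ++dy) {
            int cy = by + dy; if (cy >= ncy) cy = ncy - 1;
            double wyz = wy[dy] * wz[dz];
            for (int dx = 0; dx < 4; ++dx) {
              int cx = bx + dx; if (cx >= ncx) cx = ncx - 1;
              double w = wx[dx] * wyz;
              size_t ci = cx + (size_t)ncx * (cy + (size_t)ncy * cz);
              acc[0] += w * c[ci];
              acc[1] += w * c[ci + ncp];
              acc[2] += w * c[ci + 2 * ncp];
            }
          }
        }
        size_t vi = i + (size_t)nx * (j + (size_t)ny * k);
        o[vi] = acc[0];
        o[vi + nvox] = acc[1];
        o[vi + 2 * nvox] = acc[2];
      }
    }
  }
  return out;
}

// Adjoint of cpp_ffd_disp: accumulate a per-voxel 3-vector field onto the
// control-point lattice (used for the similarity gradient of an FFD).
// [[Rcpp::export]]
NumericVector cpp_ffd_grad(NumericVector field, IntegerVector odim,
                           IntegerVector cpdim, double spacing) {
  const int ncx = cpdim[0], ncy = cpdim[1], ncz = cpdim[2];
  const int nx = odim[0], ny = odim[1], nz = odim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const size_t ncp = (size_t)ncx * ncy * ncz;
  NumericVector out(ncp * 3);
  const double* f = field.begin();
  double* o = out.begin();
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < nz; ++k) {
    double gz = (double)k / spacing;
    int bz = (int)std::floor(gz); double tz = gz - bz;
    bspline_w(tz, wz);
    for (int j = 0; j < ny; ++j) {
      double gy = (double)j / spacing;
      int by = (int)std::floor(gy); double ty = gy - by;
      bspline_w(ty, wy);
      for (int i = 0; i < nx; ++i) {
        double gx = (double)i / spacing;
        int bx = (int)std::floor(gx); double tx = gx - bx;
        bspline_w(tx, wx);
        size_t vi = i + (size_t)nx * (j + (size_t)ny * k);
        double f0 = f[vi], f1 = f[vi + nvox], f2 = f[vi + 2 * nvox];
        for (int dz = 0; dz < 4; ++dz) {
          int cz = bz + dz; if (cz >= ncz) cz = ncz - 1;
          for (int dy = 0; dy < 4; ++dy) {
            int cy = by + dy; if (cy >= ncy) cy = ncy - 1;
            double wyz = wy[dy] * wz[dz];
            for (int dx = 0; dx < 4; ++dx) {
              int cx = bx + dx; if (cx >= ncx) cx = ncx - 1;
              double w = wx[dx] * wyz;
              size_t ci = cx + (size_t)ncx * (cy + (size_t)ncy * cz);
              o[ci] += w * f0;
              o[ci + ncp] += w * f1;
              o[ci + 2 * ncp] += w * f2;
            }
          }
        }
      }
    }
  }
  return out;
}
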