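#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D grid at continuous 0-based voxel coordinates.
// Returns `fill` when the point lies outside [0, n-1] on any axis.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) { x0 = 0; fx = 0.0; }
  if (ny == 1) { y0 = 0; fy = 0.0; }
  if (nz == 1) { z0 = 0; fz = 0.0; }
  int x1 = (nx == 1) ? x0 : x0 + 1;
  int y1 = (ny == 1) ? y0 : y0 + 1;
  int z1 = (nz == 1) ? z0 : z0 + 1;
  #define V(i, j, k) v[(size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (size_t)(k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Ray-cast line integrals of an attenuation grid onto a flat detector.
// mu: attenuation values (mm^-1) on the grid; physical position of voxel
// (i,j,k) is origin + (i*sx, j*sy, k*sz). The source sits at `src`; the
// detector is centred at `det_center` with in-plane unit axes `eu` (columns)
// and `ev` (rows) and square pixels of side `pixel_size` mm. Each pixel value
// is the midpoint-rule sum of mu along the source->pixel ray with step
// `step` mm, restricted to the grid bounding box.
// [[Rcpp::export]]
NumericMatrix cpp_raycast(NumericVector mu, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericVector src, NumericVector det_center,
                          NumericVector eu, NumericVector ev,
                          int det_cols, int det_rows,
                          double pixel_size, double step) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = mu.begin();
  NumericMatrix out(det_rows, det_cols);
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a];
    hi[a] = origin[a] + (dims[a] - 1) * spacing[a];
  }
  for (int c = 0; c < det_cols; ++c) {
    double uoff = (c + 0.5 - det_cols / 2.0) * pixel_size;
    for (int r = 0; r < det_rows; ++r) {
      double voff = (r + 0.5 - det_rows / 2.0) * pixel_size;
      double px[3], d[3];
      double len = 0.0;
      for (int a = 0; a < 3; ++a) {
        px[a] = det_center[a] + uoff * eu[a] + voff * ev[a];
        d[a] = px[a] - src[a];
        len += d[a] * d[a];
      }
      len = std::sqrt(len);
      double e[3];
      for (int a = 0; a < 3; ++a) e[a] = d[a] / len;
      // clip ray to the grid bounding box (slab method)
      double t0 = 0.0, t1 = len;
      bool miss = false;
      for (int a = 0; a < 3 && !miss; ++a) {
        if (std::fabs(e[a]) < 1e-12) {
          if (src[a] < lo[a] || src[a] > hi[a]) miss = true;
        } else {
          double ta = (lo[a] - src[a]) / e[a];
          double tb = (hi[a] - src[a]) / e[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 >= t1) miss = true;
        }
      }
      if (miss) { out(r, c) = 0.0; continue; }
      int nstep = (int)std::ceil((t1 - t0) / step);
      double acc = 0.0;
      for (int s = 0; s < nstep; ++s) {
        double t = t0 + (s + 0.5) * (t1 - t0) / nstep;
        double gx = (src[0] + t * e[0] - origin[0]) / spacing[0];
        double gy = (src[1] + t * e[1] - origin[1]) / spacing[1];
        double gz = (src[2] + t * e[2] - origin[2]) / spacing[2];
        acc += trilinear(v, nx, ny, nz, gx, gy, gz, 0.0);
      }
      out(r, c) = acc * (t1 - t0) / nstep;
    }
  }
  return out;
}

// Resample a grid through an affine index map: output voxel (i,j,k) (0-based)
// samples the input at continuous index M %*% c(i,j,k) + off, trilinearly,
// with out-of-grid fill.
// [[Rcpp::export]]
NumericVector cpp_resample_idx(NumericVector vol, IntegerVector dims_in,
                               IntegerVector dims_out, NumericMatrix M,
                               NumericVector off, double fill) {
  int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  const double *v = vol.begin();
  NumericVector out((size_t)ox * oy * oz);
  size_t p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++p) {
        double sx = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + off[0];
        double sy = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + off[1];
        double sz = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + off[2];
        out[p] = trilinear(v, nx, ny, nz, sx, sy, sz, fill);
      }
  out.attr("dim") = dims_out;
  return out;
}

// im2col for 3x3...xk cubic kernels on a (nx,ny,nz,C) array.
// Output: matrix with one row per output voxel (x fastest, then y, z) and
// columns ordered offset-fastest within channel: col = off + k^3*(c-1),
// off = kx + k*ky + k^2*kz. Zero padding `pad`, stride `stride`.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector vol, IntegerVector dims, int ksize,
                         int stride, int pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = (nx + 2 * pad - ksize) / stride + 1;
  int oy = (ny + 2 * pad - ksize) / stride + 1;
  int oz = (nz + 2 * pad - ksize) / stride + 1;
  size_t nout = (size_t)ox * oy * oz;
  int kcub = ksize * ksize * ksize;
  NumericMatrix out(nout, (size_t)kcub * nc);
  const double *v = vol.begin();
  size_t chan_stride = (size_t)nx * ny * nz;
  for (int c = 0; c < nc; ++c) {
    const double *vc = v + c * chan_stride;
    for (int kz = 0; kz < ksize; ++kz)
      for (int ky = 0; ky < ksize; ++ky)
        for (int kx = 0; kx < ksize; ++kx) {
          int col = kx + ksize * ky + ksize * ksize * kz + kcub * c;
          size_t row = 0;
          for (int z = 0; z < oz; ++z) {
            int iz = z * stride + kz - pad;
            for (int y = 0; y < oy; ++y) {
              int iy = y * stride + ky - pad;
              for (int x = 0; x < ox; ++x, ++row) {
                int ix = x * stride + kx - pad;
                if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
                  out(row, col) = 0.0;
                else
                  out(row, col) = vc[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)];
              }
            }
          }
        }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch-matrix gradients back onto the
// (nx,ny,nz,C) input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims, int ksize,
                         int stride, int pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = (nx + 2 * pad - ksize) / stride + 1;
  int oy = (ny + 2 * pad - ksize) / stride + 1;
  int oz = (nz + 2 * pad - ksize) / stride + 1;
  int kcub = ksize * ksize * ksize;
  NumericVector out((size_t)nx * ny * nz * nc);
  double *v = out.begin();
  size_t chan_stride = (size_t)nx * ny * nz;
  for (int c = 0; c < nc; ++c) {
    double *vc = v + c * chan_stride;
    for (int kz = 0; kz < ksize; ++kz)
      for (int ky = 0; ky < ksize; ++ky)
        for (int kx = 0; kx < ksize; ++kx) {
          int col = kx + ksize * ky + ksize * ksize * kz + kcub * c;
          size_t row = 0;
          for (int z = 0; z < oz; ++z) {
            int iz = z * stride + kz - pad;
            for (int y = 0; y < oy; ++y) {
              int iy = y * stride + ky - pad;
              for (int x = 0; x < ox; ++x, ++row) {
                int ix = x * stride + kx - pad;
                if (ix >= 0 && iy >= 0 && iz >= 0 && ix < nx && iy < ny && iz < nz)
                  vc[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)] += cols(row, col);
              }
            }
          }
        }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}

// 2x2x2 stride-2 max pooling on a (nx,ny,nz,C) array (dims must be even).
// Returns the pooled array and 1-based linear argmax indices into the input,
// which make the backward pass a plain scatter.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector out((size_t)ox * oy * oz * nc);
  IntegerVector amax((size_t)ox * oy * oz * nc);
  const double *v = vol.begin();
  size_t p = 0;
  for (int c = 0; c < nc; ++c) {
    size_t coff = (size_t)c * nx * ny * nz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x, ++p) {
          double best = -HUGE_VAL;
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t idx = coff + (size_t)(2 * x + dx) +
                  (size_t)nx * ((size_t)(2 * y + dy) + (size_t)ny * (2 * z + dz));
                if (v[idx] > best) { best = v[idx]; bidx = idx; }
              }
          out[p] = best;
          amax[p] = (int)(bidx + 1);
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["out"] = out, _["argmax"] = amax);
}
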