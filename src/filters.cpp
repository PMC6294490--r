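// 3D image primitives for foci detection.
// Volumes are passed as numeric vectors in R array order with dim (nz, ny, nx),
// i.e. column-major with z fastest: index = z + nz * (y + ny * x).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void blur_axis(const std::vector<double> &src, std::vector<double> &dst,
                      int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0.0) { dst = src; return; }
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    w[k + r] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += w[k + r];
  }
  for (size_t i = 0; i < w.size(); ++i) w[i] /= s;

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int zz = z, yy = y, xx = x;
          if (axis == 0)      zz = reflect_idx(z + k, nz);
          else if (axis == 1) yy = reflect_idx(y + k, ny);
          else                xx = reflect_idx(x + k, nx);
          acc += w[k + r] * src[(size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx)];
        }
        dst[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x)] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussBlur3D(NumericVector vol, IntegerVector dims,
                          double sigma_z, double sigma_y, double sigma_x) {
  if (dims.size() != 3) stop("dims must be (nz, ny, nx)");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if ((size_t)nz * ny * nx != (size_t)vol.size())
    stop("volume length does not match dims");
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  blur_axis(a, b, nz, ny, nx, 0, sigma_z);
  blur_axis(b, a, nz, ny, nx, 1, sigma_y);
  blur_axis(a, b, nz, ny, nx, 2, sigma_x);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector localMax3D(NumericVector vol, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must be (nz, ny, nx)");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if ((size_t)nz * ny * nx != (size_t)vol.size())
    stop("volume length does not match dims");
  LogicalVector out(vol.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        size_t idx = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
        double v = vol[idx];
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && ismax; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              if (vol[(size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx)] > v) {
                ismax = false; break;
              }
            }
          }
        }
        out[idx] = ismax;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
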