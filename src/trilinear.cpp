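#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation helpers shared by resampling and the
// registration metric. Coordinates are 0-based voxel indices; points up to
// a small epsilon outside the far faces are clamped onto the boundary
// cell, anything further out samples `fill`.

static inline double tri_sample(const double *a, int nx, int ny, int nz,
                                double x, double y, double z, double fill,
                                bool &ok) {
  const double eps = 1e-9;
  if (x < -eps || x > nx - 1 + eps || y < -eps || y > ny - 1 + eps ||
      z < -eps || z > nz - 1 + eps) {
    ok = false;
    return fill;
  }
  ok = true;
  int x0 = (int)std::floor(x);
  int y0 = (int)std::floor(y);
  int z0 = (int)std::floor(z);
  if (x0 < 0) x0 = 0; if (x0 > nx - 2) x0 = nx - 2;
  if (y0 < 0) y0 = 0; if (y0 > ny - 2) y0 = ny - 2;
  if (z0 < 0) z0 = 0; if (z0 > nz - 2) z0 = nz - 2;
  double dx = x - x0, dy = y - y0, dz = z - z0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double *p = a + x0 + (R_xlen_t)nx * y0 + nxy * z0;
  double c00 = p[0] * (1 - dx) + p[1] * dx;
  double c10 = p[nx] * (1 - dx) + p[nx + 1] * dx;
  double c01 = p[nxy] * (1 - dx) + p[nxy + 1] * dx;
  double c11 = p[nxy + nx] * (1 - dx) + p[nxy + nx + 1] * dx;
  return (c00 * (1 - dy) + c10 * dy) * (1 - dz) +
         (c01 * (1 - dy) + c11 * dy) * dz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector adim,
                            NumericMatrix coords, double fill) {
  const int nx = adim[0], ny = adim[1], nz = adim[2];
  const R_xlen_t n = coords.ncol();
  NumericVector out(n);
  const double *a = arr.begin();
  const double *c = coords.begin();
  bool ok;
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = tri_sample(a, nx, ny, nz, c[3 * i], c[3 * i + 1],
                        c[3 * i + 2], fill, ok);
  }
  return out;
}

// Mean squared error between `fixed` and `arr` sampled at M %*% [ijk; 1],
// with out-of-view samples compared against `fill`.
// [[Rcpp::export]]
double cpp_mse_affine(NumericVector arr, IntegerVector adim,
                      NumericMatrix M, NumericMatrix ijk,
                      NumericVector fixed, double fill) {
  const int nx = adim[0], ny = adim[1], nz = adim[2];
  const R_xlen_t n = ijk.ncol();
  const double *a = arr.begin();
  const double *g = ijk.begin();
  const double *f = fixed.begin();
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  double acc = 0.0;
  bool ok;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double u = g[3 * i], v = g[3 * i + 1], w = g[3 * i + 2];
    const double x = m00 * u + m01 * v + m02 * w + m03;
    const double y = m10 * u + m11 * v + m12 * w + m13;
    const double z = m20 * u + m21 * v + m22 * w + m23;
    const double s = tri_sample(a, nx, ny, nz, x, y, z, fill, ok);
    const double d = s - f[i];
    acc += d * d;
  }
  return acc / (double)n;
}
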