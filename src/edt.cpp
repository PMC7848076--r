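#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Anisotropic squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher). One 1D pass per axis; each pass
// uses the physical sample spacing of that axis, so voxel anisotropy is
// honored exactly.

static const double BIG = 1e30;

// 1D squared distance transform with sample spacing w.
// f: input squared costs; d: output; n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector target, IntegerVector dim,
                      NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  // initialize squared distance: 0 on target, BIG elsewhere
  for (R_xlen_t i = 0; i < n; i++) out[i] = target[i] ? 0.0 : BIG;

  std::vector<double> f, d;

  // pass along z (fastest-varying index, stride 1)
  f.resize(nz); d.resize(nz);
  for (int ix = 0; ix < nx; ix++) {
    for (int iy = 0; iy < ny; iy++) {
      const R_xlen_t base = (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
      for (int i = 0; i < nz; i++) f[i] = out[base + i];
      dt1d(f, d, nz, dz);
      for (int i = 0; i < nz; i++) out[base + i] = d[i];
    }
  }
  // pass along y (stride nz)
  f.resize(ny); d.resize(ny);
  for (int ix = 0; ix < nx; ix++) {
    for (int iz = 0; iz < nz; iz++) {
      const R_xlen_t base = iz + (R_xlen_t)nz * ny * ix;
      for (int i = 0; i < ny; i++) f[i] = out[base + (R_xlen_t)nz * i];
      dt1d(f, d, ny, dy);
      for (int i = 0; i < ny; i++) out[base + (R_xlen_t)nz * i] = d[i];
    }
  }
  // pass along x (stride nz*ny)
  f.resize(nx); d.resize(nx);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int iy = 0; iy < ny; iy++) {
    for (int iz = 0; iz < nz; iz++) {
      const R_xlen_t base = iz + (R_xlen_t)nz * iy;
      for (int i = 0; i < nx; i++) f[i] = out[base + sx * i];
      dt1d(f, d, nx, dx);
      for (int i = 0; i < nx; i++) out[base + sx * i] = d[i];
    }
  }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = out[i] >= BIG ? R_PosInf : std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}
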