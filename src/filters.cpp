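#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3D median filter with an axis-aligned box window (radius per axis, in
// voxels). Boundaries are handled by window clipping, so constant images are
// preserved exactly.

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector image, IntegerVector dim,
                           IntegerVector radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int rz = radius[0], ry = radius[1], rx = radius[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((size_t)(2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int ix = 0; ix < nx; ix++) {
    const int x0 = std::max(0, ix - rx), x1 = std::min(nx - 1, ix + rx);
    for (int iy = 0; iy < ny; iy++) {
      const int y0 = std::max(0, iy - ry), y1 = std::min(ny - 1, iy + ry);
      for (int iz = 0; iz < nz; iz++) {
        const int z0 = std::max(0, iz - rz), z1 = std::min(nz - 1, iz + rz);
        buf.clear();
        for (int x = x0; x <= x1; x++)
          for (int y = y0; y <= y1; y++) {
            const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            for (int z = z0; z <= z1; z++) buf.push_back(image[base + z]);
          }
        const size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                           buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
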