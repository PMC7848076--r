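#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling with 6- or 26-connectivity.
// Components are relabeled 1..K ordered by the (z, y, x) lexicographic
// position of each component's first voxel, so labels are deterministic
// and independent of internal scan order.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<int> dzs, dys, dxs;
  for (int ddz = -1; ddz <= 1; ddz++)
    for (int ddy = -1; ddy <= 1; ddy++)
      for (int ddx = -1; ddx <= 1; ddx++) {
        if (ddz == 0 && ddy == 0 && ddx == 0) continue;
        const int manh = std::abs(ddz) + std::abs(ddy) + std::abs(ddx);
        if (connectivity == 6 && manh > 1) continue;
        dzs.push_back(ddz); dys.push_back(ddy); dxs.push_back(ddx);
      }
  const int nn = (int)dzs.size();

  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> firstVoxelKey;  // (z*ny + y)*nx + x of first voxel
  int next = 0;
  for (R_xlen_t i0 = 0; i0 < n; i0++) {
    if (!mask[i0] || lab[i0] != 0) continue;
    next++;
    lab[i0] = next;
    R_xlen_t bestKey = -1;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      const R_xlen_t i = stack.back();
      stack.pop_back();
      const int iz = (int)(i % nz);
      const int iy = (int)((i / nz) % ny);
      const int ix = (int)(i / ((R_xlen_t)nz * ny));
      const R_xlen_t key = ((R_xlen_t)iz * ny + iy) * nx + ix;
      if (bestKey < 0 || key < bestKey) bestKey = key;
      for (int k = 0; k < nn; k++) {
        const int jz = iz + dzs[k], jy = iy + dys[k], jx = ix + dxs[k];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
          continue;
        const R_xlen_t j = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
    firstVoxelKey.push_back(bestKey);
  }

  // order labels by first-voxel (z, y, x)
  std::vector<int> order(next);
  for (int k = 0; k < next; k++) order[k] = k;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return firstVoxelKey[a] < firstVoxelKey[b];
  });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; r++) remap[order[r] + 1] = r + 1;
  for (R_xlen_t i = 0; i < n; i++)
    if (lab[i] != 0) lab[i] = remap[lab[i]];

  lab.attr("dim") = dim;
  return lab;
}
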