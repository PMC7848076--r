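#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded watershed by priority flooding (Meyer). Voxels are flooded in order
// of increasing image value; ties are broken by insertion order, which makes
// the result deterministic for a given seed volume. 6-connectivity.

struct QItem {
  double value;
  unsigned long long order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector image, IntegerVector seeds,
                            IntegerVector dim,
                            Rcpp::Nullable<LogicalVector> mask = R_NilValue) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector msk;
  const bool hasMask = mask.isNotNull();
  if (hasMask) msk = mask.get();
  IntegerVector lab(n);
  for (R_xlen_t i = 0; i < n; i++) lab[i] = seeds[i];

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long long counter = 0;
  for (R_xlen_t i = 0; i < n; i++)
    if (seeds[i] > 0) pq.push({image[i], counter++, i});

  static const int dzs[6] = {-1, 1, 0, 0, 0, 0};
  static const int dys[6] = {0, 0, -1, 1, 0, 0};
  static const int dxs[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    const R_xlen_t i = it.idx;
    const int iz = (int)(i % nz);
    const int iy = (int)((i / nz) % ny);
    const int ix = (int)(i / ((R_xlen_t)nz * ny));
    for (int k = 0; k < 6; k++) {
      const int jz = iz + dzs[k], jy = iy + dys[k], jx = ix + dxs[k];
      if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
        continue;
      const R_xlen_t j = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
      if (lab[j] == 0 && (!hasMask || msk[j])) {
        lab[j] = lab[i];
        pq.push({image[j], counter++, j});
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
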