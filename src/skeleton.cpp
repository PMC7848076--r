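#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3D curve thinning by iterative removal of simple border points.
// A voxel is "simple" (deletable without changing topology) iff
//  - its 26-neighborhood (center excluded) contains exactly one
//    26-connected foreground component, and
//  - the background restricted to its 18-neighborhood contains exactly one
//    6-connected component that touches a face neighbor of the center
// (topological numbers T26 = T6bar = 1, Bertrand/Malandain characterization).
// Endpoints (<= 1 foreground 26-neighbor) are preserved so that curve
// skeletons keep their full extent. Deletion proceeds in six directional
// subiterations with sequential rechecking, which keeps the result
// deterministic and topology-preserving.

// local cube index: (dz+1) + 3*(dy+1) + 9*(dx+1); center = 13
static inline int cidx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

static int count26ForegroundComponents(const bool cube[27]) {
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    comps++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      const int c = stack[--top];
      const int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int z = cz - 1; z <= cz + 1; z++)
        for (int y = cy - 1; y <= cy + 1; y++)
          for (int x = cx - 1; x <= cx + 1; x++) {
            if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
            const int d = z + 3 * y + 9 * x;
            if (d == 13 || d == c || seen[d] || !cube[d]) continue;
            seen[d] = true;
            stack[top++] = d;
          }
    }
  }
  return comps;
}

static int count6BackgroundComponents(const bool cube[27]) {
  // 18-neighborhood = offsets with |dz|+|dy|+|dx| in {1, 2}
  bool in18[27];
  for (int s = 0; s < 27; s++) {
    const int z = s % 3 - 1, y = (s / 3) % 3 - 1, x = s / 9 - 1;
    const int manh = std::abs(z) + std::abs(y) + std::abs(x);
    in18[s] = (manh == 1 || manh == 2);
  }
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int comps = 0;
  int stack[27];
  static const int fz[6] = {-1, 1, 0, 0, 0, 0};
  static const int fy[6] = {0, 0, -1, 1, 0, 0};
  static const int fx[6] = {0, 0, 0, 0, -1, 1};
  for (int fi = 0; fi < 6; fi++) {
    const int s = cidx(fz[fi], fy[fi], fx[fi]);
    if (cube[s] || seen[s]) continue;  // need background face neighbor
    comps++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      const int c = stack[--top];
      const int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int k = 0; k < 6; k++) {
        const int z = cz + fz[k], y = cy + fy[k], x = cx + fx[k];
        if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
        const int d = z + 3 * y + 9 * x;
        if (d == 13 || !in18[d] || seen[d] || cube[d]) continue;
        seen[d] = true;
        stack[top++] = d;
      }
    }
  }
  return comps;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dim,
                                int maxIter = -1) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; i++) fg[i] = mask[i] ? 1 : 0;

  auto at = [&](int iz, int iy, int ix) -> char {
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
      return 0;
    return fg[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
  };
  auto fillCube = [&](int iz, int iy, int ix, bool cube[27]) {
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          cube[cidx(dz, dy, dx)] = at(iz + dz, iy + dy, ix + dx) != 0;
  };
  auto nFgNeighbors = [&](int iz, int iy, int ix) {
    int cnt = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dz && !dy && !dx) continue;
          cnt += at(iz + dz, iy + dy, ix + dx);
        }
    return cnt;
  };
  auto isSimple = [&](int iz, int iy, int ix) {
    bool cube[27];
    fillCube(iz, iy, ix, cube);
    if (count26ForegroundComponents(cube) != 1) return false;
    return count6BackgroundComponents(cube) == 1;
  };
  // Line-end protection: a voxel whose foreground neighbors all lie in one
  // face-adjacent half-space (all at dz=+1, or all at dz=-1, etc.) is the
  // tip of a digital curve; deleting such tips one after another would eat
  // a ribbon from its end instead of flattening it to its medial line.
  auto isLineEnd = [&](int iz, int iy, int ix) {
    int cnt = 0;
    bool allZp = true, allZm = true, allYp = true, allYm = true;
    bool allXp = true, allXm = true;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dz && !dy && !dx) continue;
          if (!at(iz + dz, iy + dy, ix + dx)) continue;
          cnt++;
          if (dz != 1) allZp = false;
          if (dz != -1) allZm = false;
          if (dy != 1) allYp = false;
          if (dy != -1) allYm = false;
          if (dx != 1) allXp = false;
          if (dx != -1) allXm = false;
        }
    if (cnt <= 1) return true;  // classic endpoint or isolated voxel
    return allZp || allZm || allYp || allYm || allXp || allXm;
  };

  static const int dirz[6] = {-1, 1, 0, 0, 0, 0};
  static const int diry[6] = {0, 0, -1, 1, 0, 0};
  static const int dirx[6] = {0, 0, 0, 0, -1, 1};

  // iterate over the (shrinking) foreground only, not the full volume
  std::vector<R_xlen_t> live;
  for (R_xlen_t i = 0; i < n; i++)
    if (fg[i]) live.push_back(i);

  std::vector<R_xlen_t> cand;
  bool changed = true;
  int iter = 0;
  bool stop = false;
  while (changed && !stop) {
    changed = false;
    size_t w = 0;
    for (size_t r = 0; r < live.size(); r++)
      if (fg[live[r]]) live[w++] = live[r];
    live.resize(w);
    for (int d = 0; d < 6; d++) {
      if (maxIter >= 0 && iter++ >= maxIter) { stop = true; break; }
      cand.clear();
      for (size_t li = 0; li < live.size(); li++) {
        const R_xlen_t i = live[li];
        if (!fg[i]) continue;
        const int iz = (int)(i % nz);
        const int iy = (int)((i / nz) % ny);
        const int ix = (int)(i / ((R_xlen_t)nz * ny));
        if (at(iz + dirz[d], iy + diry[d], ix + dirx[d])) continue;  // border?
        // Plate guard: a border point of a plate perpendicular to d may only
        // be removed once the peeling front (the plate's rim) reaches it --
        // it must have a background neighbor within the plate plane.
        // Without this, a 1-voxel-thick sheet is consumed from one corner in
        // a single subiteration and the medial line is lost.
        bool edgeInPlane = false;
        for (int a1 = -1; a1 <= 1 && !edgeInPlane; a1++)
          for (int a2 = -1; a2 <= 1 && !edgeInPlane; a2++) {
            if (a1 == 0 && a2 == 0) continue;
            int pz = iz, py = iy, px = ix;
            if (dirz[d] != 0) { py += a1; px += a2; }
            else if (diry[d] != 0) { pz += a1; px += a2; }
            else { pz += a1; py += a2; }
            if (!at(pz, py, px)) edgeInPlane = true;
          }
        if (!edgeInPlane) continue;
        if (isLineEnd(iz, iy, ix)) continue;
        if (!isSimple(iz, iy, ix)) continue;
        cand.push_back(i);
      }
      // sequential deletion with recheck preserves topology
      for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ci++) {
        const R_xlen_t i = cand[ci];
        const int iz = (int)(i % nz);
        const int iy = (int)((i / nz) % ny);
        const int ix = (int)(i / ((R_xlen_t)nz * ny));
        if (isLineEnd(iz, iy, ix)) continue;
        if (!isSimple(iz, iy, ix)) continue;
        fg[i] = 0;
        changed = true;
      }
    }
  }

  // Final cleanup: the line-end guard can leave small rosettes (remnants of
  // tube end caps). At this stage everything is a 1-voxel-wide curve, where
  // interior voxels are non-simple (removal would disconnect), so peeling
  // with only the classic endpoint rule removes rosette voxels and nothing
  // else.
  changed = !stop;
  while (changed) {
    changed = false;
    for (size_t li = 0; li < live.size(); li++) {
      const R_xlen_t i = live[li];
      if (!fg[i]) continue;
      const int iz = (int)(i % nz);
      const int iy = (int)((i / nz) % ny);
      const int ix = (int)(i / ((R_xlen_t)nz * ny));
      if (nFgNeighbors(iz, iy, ix) <= 1) continue;
      if (!isSimple(iz, iy, ix)) continue;
      fg[i] = 0;
      changed = true;
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
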