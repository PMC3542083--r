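#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
#include <tuple>
using namespace Rcpp;

// Topology-preserving 3D thinning to a curve skeleton.
//
// A foreground voxel p is "simple" (deletable without changing topology,
// (26,6)-connectivity) when (a) the foreground in its 26-neighbourhood minus
// p forms exactly one 26-connected component and (b) the background in its
// 18-neighbourhood forms exactly one 6-connected component that is 6-adjacent
// to p.  Border voxels are deleted in increasing distance-transform order
// (distance-ordered homotopic thinning), so the surviving curve runs along
// the medial axis; curve endpoints (exactly one foreground 26-neighbour) are
// never removed.

static inline int off27(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

static bool simple_point(const std::array<uint8_t, 27>& nb) {
  // (a) one 26-component of foreground in N26 \ {p}
  std::array<uint8_t, 27> seen{};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    // BFS over 26-adjacency inside the 3x3x3 block
    std::array<int, 27> stack; int top = 0;
    stack[top++] = s; seen[s] = 1;
    while (top) {
      int q = stack[--top];
      int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int rx = qx + dx, ry = qy + dy, rz = qz + dz;
            if (rx < 0 || ry < 0 || rz < 0 || rx > 2 || ry > 2 || rz > 2)
              continue;
            int r = rx + 3 * (ry + 3 * rz);
            if (r == 13 || seen[r] || !nb[r]) continue;
            seen[r] = 1; stack[top++] = r;
          }
    }
  }
  if (comps != 1) return false;
  // (b) one 6-component of background in N18 that touches p 6-adjacently
  auto in18 = [](int s) {
    if (s == 13) return false;
    int dx = s % 3 - 1, dy = (s / 3) % 3 - 1, dz = s / 9 - 1;
    return std::abs(dx) + std::abs(dy) + std::abs(dz) <= 2;
  };
  std::array<uint8_t, 27> seenb{};
  int bcomps = 0;
  static const int six[6] = {off27(-1, 0, 0), off27(1, 0, 0), off27(0, -1, 0),
                             off27(0, 1, 0),  off27(0, 0, -1), off27(0, 0, 1)};
  for (int si = 0; si < 6; ++si) {
    int s = six[si];
    if (nb[s] || seenb[s]) continue;
    ++bcomps;
    if (bcomps > 1) return false;
    std::array<int, 27> stack; int top = 0;
    stack[top++] = s; seenb[s] = 1;
    while (top) {
      int q = stack[--top];
      int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int t = 0; t < 6; ++t) {
        int rx = qx + d6[t][0], ry = qy + d6[t][1], rz = qz + d6[t][2];
        if (rx < 0 || ry < 0 || rz < 0 || rx > 2 || ry > 2 || rz > 2) continue;
        int r = rx + 3 * (ry + 3 * rz);
        if (!in18(r) || seenb[r] || nb[r]) continue;
        seenb[r] = 1; stack[top++] = r;
      }
    }
  }
  return bcomps == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin_volume(LogicalVector mask, IntegerVector dims,
                              NumericVector priority) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<uint8_t> fg(n);
  for (size_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  auto get = [&](int i, int j, int k) -> uint8_t {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return fg[idx(i, j, k)];
  };
  auto neighborhood = [&](int i, int j, int k, std::array<uint8_t, 27>& nb) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[off27(dx, dy, dz)] = get(i + dx, j + dy, k + dz);
  };
  auto n26count = [&](const std::array<uint8_t, 27>& nb) {
    int c = 0;
    for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
    return c;
  };
  auto is_border = [&](int i, int j, int k) {
    return !get(i - 1, j, k) || !get(i + 1, j, k) || !get(i, j - 1, k) ||
           !get(i, j + 1, k) || !get(i, j, k - 1) || !get(i, j, k + 1);
  };
  // distance-ordered homotopic thinning: border voxels are deleted in
  // increasing distance-transform order (re-checked sequentially), so curve
  // endpoints freeze near the medial axis at a depth ~ the local radius
  // ties in the distance transform are broken by a coordinate hash rather
  // than raster order, so the erosion has no systematic directional bias
  auto mix = [](size_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33; return x;
  };
  std::vector<std::tuple<double, size_t, size_t>> cand;
  bool changed = true;
  std::array<uint8_t, 27> nb;
  while (changed) {
    changed = false;
    cand.clear();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t p = idx(i, j, k);
          if (fg[p] && is_border(i, j, k))
            cand.emplace_back(priority[p], mix(p), p);
        }
    std::sort(cand.begin(), cand.end());
    for (auto& cp : cand) {
      size_t p = std::get<2>(cp);
      if (!fg[p]) continue;
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((size_t)nx * ny));
      if (!is_border(i, j, k)) continue;
      neighborhood(i, j, k, nb);
      if (n26count(nb) <= 1) continue;      // curve endpoint: keep
      if (simple_point(nb)) { fg[p] = 0; changed = true; }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}
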