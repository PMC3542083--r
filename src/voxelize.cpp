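#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxelize a closed triangulated surface by vertical ray parity.
//
// For every (x, y) column of voxel centres a ray along +z collects the z
// values where it crosses surface triangles; voxel centres between an odd
// and the following even crossing are inside.  Ray origins are jittered by
// an irrational sub-voxel offset so rays never hit triangle edges exactly;
// an odd number of crossings in any column means the surface leaks.
//
// Returns a logical array; attribute "leaky" flags parity failure.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                IntegerVector dims, NumericVector pitch,
                                NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = pitch[0], hy = pitch[1], hz = pitch[2];
  const double jx = 0.5 + 1e-4 * std::sqrt(2.0) ;   // irrational jitter
  const double jy = 0.5 + 1e-4 * std::sqrt(3.0);
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((xmin - origin[0]) / hx - jx));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - origin[0]) / hx - jx) + 1);
    int j0 = std::max(0, (int)std::floor((ymin - origin[1]) / hy - jy));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - origin[1]) / hy - jy) + 1);
    double d = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (d == 0.0) continue;                       // vertical triangle: no z crossing
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + (j + jy) * hy;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + (i + jx) * hx;
        // barycentric test in the xy projection
        double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        double z = l1 * az + l2 * bz + l3 * cz;
        cross[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  bool leaky = false;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto& zs = cross[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      if (zs.size() % 2 != 0) { leaky = true; continue; }
      for (size_t s = 0; s + 1 < zs.size(); s += 2) {
        int k0 = std::max(0, (int)std::ceil((zs[s] - origin[2]) / hz - 0.5));
        int k1 = std::min(nz - 1, (int)std::floor((zs[s + 1] - origin[2]) / hz - 0.5));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  out.attr("dim") = dims;
  out.attr("leaky") = leaky;
  return out;
}
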