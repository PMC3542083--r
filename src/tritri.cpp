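#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Triangle-triangle intersection (Moller 1997 interval test) used to detect
// self-intersection of the colony surface during accretion -- the physical
// analogue of branch fusion (anastomosis), which the growth model does not
// simulate and therefore reports instead of resolving.

typedef double Vec3[3];

static inline void sub(Vec3 r, const double* a, const double* b) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void cross(Vec3 r, const Vec3 a, const Vec3 b) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const Vec3 a, const Vec3 b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static void isect_interval(double vv0, double vv1, double vv2,
                           double d0, double d1, double d2,
                           double* t0, double* t1) {
  // d0 and d1/d2 have opposite signs combinations handled by caller
  *t0 = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
  *t1 = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
}

// 2D coplanar overlap: separating-axis test on the dominant projection
static bool coplanar_overlap(const double* V0, const double* V1, const double* V2,
                             const double* U0, const double* U1, const double* U2,
                             const Vec3 N) {
  int i0, i1;
  double A[3] = {std::fabs(N[0]), std::fabs(N[1]), std::fabs(N[2])};
  if (A[0] > A[1]) { if (A[0] > A[2]) { i0 = 1; i1 = 2; } else { i0 = 0; i1 = 1; } }
  else { if (A[2] > A[1]) { i0 = 0; i1 = 1; } else { i0 = 0; i1 = 2; } }
  double t1[3][2] = {{V0[i0], V0[i1]}, {V1[i0], V1[i1]}, {V2[i0], V2[i1]}};
  double t2[3][2] = {{U0[i0], U0[i1]}, {U1[i0], U1[i1]}, {U2[i0], U2[i1]}};
  auto sat = [](double a[3][2], double b[3][2]) {
    for (int e = 0; e < 3; ++e) {
      double ex = a[(e + 1) % 3][0] - a[e][0];
      double ey = a[(e + 1) % 3][1] - a[e][1];
      double nx = -ey, ny = ex;
      double amin = 1e300, amax = -1e300, bmin = 1e300, bmax = -1e300;
      for (int v = 0; v < 3; ++v) {
        double pa = nx * a[v][0] + ny * a[v][1];
        double pb = nx * b[v][0] + ny * b[v][1];
        amin = std::min(amin, pa); amax = std::max(amax, pa);
        bmin = std::min(bmin, pb); bmax = std::max(bmax, pb);
      }
      if (amax < bmin || bmax < amin) return true;
    }
    return false;
  };
  return !(sat(t1, t2) || sat(t2, t1));
}

static bool tri_tri_intersect(const double* V0, const double* V1, const double* V2,
                              const double* U0, const double* U1, const double* U2,
                              double eps) {
  Vec3 E1, E2, N1, N2, D;
  sub(E1, V1, V0); sub(E2, V2, V0); cross(N1, E1, E2);
  double d1 = -dot(N1, V0);
  double du0 = dot(N1, U0) + d1, du1 = dot(N1, U1) + d1, du2 = dot(N1, U2) + d1;
  if (std::fabs(du0) < eps) du0 = 0; if (std::fabs(du1) < eps) du1 = 0;
  if (std::fabs(du2) < eps) du2 = 0;
  if (du0 * du1 > 0 && du0 * du2 > 0) return false;
  sub(E1, U1, U0); sub(E2, U2, U0); cross(N2, E1, E2);
  double d2 = -dot(N2, U0);
  double dv0 = dot(N2, V0) + d2, dv1 = dot(N2, V1) + d2, dv2 = dot(N2, V2) + d2;
  if (std::fabs(dv0) < eps) dv0 = 0; if (std::fabs(dv1) < eps) dv1 = 0;
  if (std::fabs(dv2) < eps) dv2 = 0;
  if (dv0 * dv1 > 0 && dv0 * dv2 > 0) return false;
  cross(D, N1, N2);
  double max = std::fabs(D[0]); int index = 0;
  if (std::fabs(D[1]) > max) { max = std::fabs(D[1]); index = 1; }
  if (std::fabs(D[2]) > max) { max = std::fabs(D[2]); index = 2; }
  if (max < eps) {                     // coplanar
    if (du0 == 0 && du1 == 0 && du2 == 0)
      return coplanar_overlap(V0, V1, V2, U0, U1, U2, N1);
    return false;
  }
  double vp0 = V0[index], vp1 = V1[index], vp2 = V2[index];
  double up0 = U0[index], up1 = U1[index], up2 = U2[index];
  double a0, a1, b0, b1;
  // arrange so the lone-signed vertex comes first
  auto arrange = [](double& p0, double& p1, double& p2,
                    double& e0, double& e1, double& e2) -> bool {
    if (e0 * e1 > 0) { std::swap(p0, p2); std::swap(e0, e2); }
    else if (e0 * e2 > 0) { std::swap(p0, p1); std::swap(e0, e1); }
    else if (e1 * e2 > 0 || e0 != 0) { /* p0 already alone */ }
    else if (e1 != 0) { std::swap(p0, p1); std::swap(e0, e1); }
    else if (e2 != 0) { std::swap(p0, p2); std::swap(e0, e2); }
    else return false;                 // all zero: coplanar, handled above
    return true;
  };
  double vq0 = vp0, vq1 = vp1, vq2 = vp2, dq0 = dv0, dq1 = dv1, dq2 = dv2;
  double uq0 = up0, uq1 = up1, uq2 = up2, eq0 = du0, eq1 = du1, eq2 = du2;
  if (!arrange(vq0, vq1, vq2, dq0, dq1, dq2)) return false;
  if (!arrange(uq0, uq1, uq2, eq0, eq1, eq2)) return false;
  isect_interval(vq0, vq1, vq2, dq0, dq1, dq2, &a0, &a1);
  isect_interval(uq0, uq1, uq2, eq0, eq1, eq2, &b0, &b1);
  if (a0 > a1) std::swap(a0, a1);
  if (b0 > b1) std::swap(b0, b1);
  return !(a1 < b0 || b1 < a0);
}

// [[Rcpp::export]]
IntegerMatrix cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  const int m = F.nrow();
  // broad phase: hash triangle bounding boxes on a uniform grid
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  double meanedge = 0;
  for (int t = 0; t < m; ++t)
    for (int c = 0; c < 3; ++c) {
      int a = F(t, c) - 1, b = F(t, (c + 1) % 3) - 1;
      double dx = V(a, 0) - V(b, 0), dy = V(a, 1) - V(b, 1), dz = V(a, 2) - V(b, 2);
      meanedge += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  meanedge /= (3.0 * std::max(m, 1));
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(i, d)); hi[d] = std::max(hi[d], V(i, d));
    }
  double cell = std::max(meanedge * 1.5, 1e-12);
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [](long long i, long long j, long long k) {
    return (i * 73856093LL) ^ (j * 19349663LL) ^ (k * 83492791LL);
  };
  std::vector<std::array<int, 6>> tbox(m);
  for (int t = 0; t < m; ++t) {
    double bl[3] = {1e300, 1e300, 1e300}, bh[3] = {-1e300, -1e300, -1e300};
    for (int c = 0; c < 3; ++c) {
      int a = F(t, c) - 1;
      for (int d = 0; d < 3; ++d) {
        bl[d] = std::min(bl[d], V(a, d)); bh[d] = std::max(bh[d], V(a, d));
      }
    }
    for (int d = 0; d < 3; ++d) {
      tbox[t][d] = (int)std::floor((bl[d] - lo[d]) / cell);
      tbox[t][3 + d] = (int)std::floor((bh[d] - lo[d]) / cell);
    }
    for (int i = tbox[t][0]; i <= tbox[t][3]; ++i)
      for (int j = tbox[t][1]; j <= tbox[t][4]; ++j)
        for (int k = tbox[t][2]; k <= tbox[t][5]; ++k)
          grid[key(i, j, k)].push_back(t);
  }
  std::vector<std::pair<int, int>> hits;
  std::vector<std::pair<int, int>> cand;
  for (auto& kv : grid) {
    auto& v = kv.second;
    for (size_t a = 0; a < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b)
        cand.emplace_back(std::min(v[a], v[b]), std::max(v[a], v[b]));
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  double eps = 1e-12 * meanedge;
  for (auto& pr : cand) {
    int t1 = pr.first, t2 = pr.second;
    bool share = false;
    for (int c1 = 0; c1 < 3 && !share; ++c1)
      for (int c2 = 0; c2 < 3; ++c2)
        if (F(t1, c1) == F(t2, c2)) { share = true; break; }
    if (share) continue;
    double A[3][3], B[3][3];
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d) {
        A[c][d] = V(F(t1, c) - 1, d);
        B[c][d] = V(F(t2, c) - 1, d);
      }
    if (tri_tri_intersect(A[0], A[1], A[2], B[0], B[1], B[2], eps))
      hits.emplace_back(t1 + 1, t2 + 1);
  }
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first; out(i, 1) = hits[i].second;
  }
  return out;
}
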