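#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Steady advection-diffusion of nutrient on the staggered flow field:
// cell-centred finite volumes, first-order upwind convection (unconditionally
// monotone, so the discrete maximum principle holds), central diffusion,
// solved by SOR with automatic fallback to Gauss-Seidel if over-relaxation
// stalls.  Cell codes: 0 fluid (unknown), 1 colony/substratum solid (c = 0),
// 2 far-field (c = cb).  facec[f] gives the Dirichlet value on domain face f
// (order x-,x+,y-,y+,z-,z+); NA means zero-gradient (no-flux with upwind
// outflow).

// [[Rcpp::export]]
List cpp_solve_transport(IntegerVector cellcode, IntegerVector dims,
                         NumericVector pitch,
                         NumericVector u, NumericVector v, NumericVector w,
                         double D, double cb, NumericVector facec,
                         double tol, int maxsweep, double omega,
                         NumericVector c_init) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = pitch[0], hy = pitch[1], hz = pitch[2];
  const double Ax = hy * hz, Ay = hx * hz, Az = hx * hy;
  const double Dx = D * Ax / hx, Dy = D * Ay / hy, Dz = D * Az / hz;
  const size_t np = (size_t)nx * ny * nz;
  auto pid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  auto uid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)(nx + 1) * (j + (size_t)ny * k);
  };
  auto vid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)(ny + 1) * k);
  };
  auto wid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  const int* code = INTEGER(cellcode);
  std::vector<double> c(np, 0.0);
  if (c_init.size() == (R_xlen_t)np) std::copy(c_init.begin(), c_init.end(), c.begin());
  for (size_t s = 0; s < np; ++s) {
    if (code[s] == 1) c[s] = 0.0;
    else if (code[s] == 2) c[s] = cb;
  }
  bool has_u = u.size() > 1;
  auto U = [&](int i, int j, int k) { return has_u ? u[uid(i, j, k)] : 0.0; };
  auto V = [&](int i, int j, int k) { return has_u ? v[vid(i, j, k)] : 0.0; };
  auto W = [&](int i, int j, int k) { return has_u ? w[wid(i, j, k)] : 0.0; };

  double res0 = -1, res = 0, prev = 1e300, bsum = 0;
  int sweep = 0;
  bool converged = false;
  std::vector<double> hist;
  for (sweep = 0; sweep < maxsweep; ++sweep) {
    res = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = pid(i, j, k);
          if (code[id] != 0) continue;
          double b = 0, aP_extra = 0, sum = 0, asum = 0;
          double Fe = U(i + 1, j, k) * Ax, Fw = U(i, j, k) * Ax;
          double Fn = V(i, j + 1, k) * Ay, Fs = V(i, j, k) * Ay;
          double Ft = W(i, j, k + 1) * Az, Fb = W(i, j, k) * Az;
          aP_extra = (Fe - Fw) + (Fn - Fs) + (Ft - Fb);
          // interior links: colony (solid) neighbours absorb at the shared
          // face (half-link Dirichlet c = 0); fluid/far-field neighbours use
          // the full centre-to-centre link
          auto link = [&](bool inrange, size_t nbid, double Dd, double Fin,
                          int face) {
            if (inrange) {
              if (code[nbid] == 1) { asum += 2 * Dd + std::max(Fin, 0.0); }
              else { double a = Dd + std::max(Fin, 0.0); asum += a; sum += a * c[nbid]; }
            } else if (R_finite(facec[face])) {
              double a = 2 * Dd + std::max(Fin, 0.0);
              asum += a; b += a * facec[face];
            }
          };
          link(i + 1 < nx, i + 1 < nx ? pid(i + 1, j, k) : 0, Dx, -Fe, 1);
          link(i - 1 >= 0, i - 1 >= 0 ? pid(i - 1, j, k) : 0, Dx, Fw, 0);
          link(j + 1 < ny, j + 1 < ny ? pid(i, j + 1, k) : 0, Dy, -Fn, 3);
          link(j - 1 >= 0, j - 1 >= 0 ? pid(i, j - 1, k) : 0, Dy, Fs, 2);
          link(k + 1 < nz, k + 1 < nz ? pid(i, j, k + 1) : 0, Dz, -Ft, 5);
          link(k - 1 >= 0, k - 1 >= 0 ? pid(i, j, k - 1) : 0, Dz, Fb, 4);
          double aP = asum + std::max(aP_extra, 0.0);
          if (aP <= 0) aP = 1e-300;
          double r = aP * c[id] - sum - b;
          res += std::fabs(r);
          if (sweep == 0) bsum += std::fabs(b) + std::fabs(aP) * cb;
          c[id] -= omega * r / aP;
        }
    if (res0 < 0) res0 = std::max(std::max(res, bsum), 1e-300);
    hist.push_back(res / res0);
    if (res / res0 <= tol || res <= 1e-300) { converged = true; break; }
    // SOR residuals are not monotone; back off over-relaxation only on
    // clear divergence
    prev = std::min(prev, res);
    if (res > 20 * prev && omega > 1.0) { omega = 1.0; prev = res; }
    if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector out(np);
  std::copy(c.begin(), c.end(), out.begin());
  out.attr("dim") = dims;
  return List::create(_["c"] = out, _["sweeps"] = sweep,
                      _["converged"] = converged,
                      _["residual"] = wrap(hist));
}

// Trilinear interpolation of a cell-centred field at arbitrary points;
// samples are clamped to the domain interior.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims,
                            NumericVector origin, NumericVector pitch,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto pid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  NumericVector out(pts.nrow());
  for (int s = 0; s < pts.nrow(); ++s) {
    double gx = (pts(s, 0) - origin[0]) / pitch[0] - 0.5;
    double gy = (pts(s, 1) - origin[1]) / pitch[1] - 0.5;
    double gz = (pts(s, 2) - origin[2]) / pitch[2] - 0.5;
    gx = std::min(std::max(gx, 0.0), nx - 1.0);
    gy = std::min(std::max(gy, 0.0), ny - 1.0);
    gz = std::min(std::max(gz, 0.0), nz - 1.0);
    int i0 = std::min((int)gx, nx - 2 < 0 ? 0 : nx - 2);
    int j0 = std::min((int)gy, ny - 2 < 0 ? 0 : ny - 2);
    int k0 = std::min((int)gz, nz - 2 < 0 ? 0 : nz - 2);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double c00 = field[pid(i0, j0, k0)] * (1 - fx) + field[pid(i1, j0, k0)] * fx;
    double c10 = field[pid(i0, j1, k0)] * (1 - fx) + field[pid(i1, j1, k0)] * fx;
    double c01 = field[pid(i0, j0, k1)] * (1 - fx) + field[pid(i1, j0, k1)] * fx;
    double c11 = field[pid(i0, j1, k1)] * (1 - fx) + field[pid(i1, j1, k1)] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[s] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
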