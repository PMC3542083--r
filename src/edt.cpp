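#include <Rcpp.h>
#include <vector>
#include <array>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2004) on
// samples at positions x_i = i * s.  f holds squared distances; in place.
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double sp = (f[q] + xq * xq - f[v[k]] - xv * xv) / sden;
      if (sp <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = sp; z[k + 1] = INF; break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  f = d;
}

// Euclidean distance transform of a binary volume: distance (in metres)
// from each foreground voxel centre to the nearest background voxel centre,
// with anisotropic voxel pitch.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      f.assign(nx, 0.0);
      for (int i = 0; i < nx; ++i) f[i] = g[idx(i, j, k)];
      f.resize(nx); d.resize(nx);
      dt1d(f, pitch[0], d, v, z);
      for (int i = 0; i < nx; ++i) g[idx(i, j, k)] = f[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      f.resize(ny); d.resize(ny);
      for (int j = 0; j < ny; ++j) f[j] = g[idx(i, j, k)];
      dt1d(f, pitch[1], d, v, z);
      for (int j = 0; j < ny; ++j) g[idx(i, j, k)] = f[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      f.resize(nz); d.resize(nz);
      for (int k = 0; k < nz; ++k) f[k] = g[idx(i, j, k)];
      dt1d(f, pitch[2], d, v, z);
      for (int k = 0; k < nz; ++k) g[idx(i, j, k)] = f[k];
    }
  NumericVector out((R_xlen_t)g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a binary volume (6- or 26-connectivity).
// Labels are 1..ncomp in decreasing component size order (label 1 largest).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<size_t> stack, sizes_order;
  std::vector<long> csize;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = idx(i, j, k);
        if (!mask[p] || lab[p]) continue;
        ++next;
        long sz = 0;
        stack.clear(); stack.push_back(p); lab[p] = next;
        while (!stack.empty()) {
          size_t q = stack.back(); stack.pop_back(); ++sz;
          int qi = (int)(q % nx), qj = (int)((q / nx) % ny), qk = (int)(q / ((size_t)nx * ny));
          for (auto& o : offs) {
            int ii = qi + o[0], jj = qj + o[1], kk = qk + o[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t r = idx(ii, jj, kk);
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
        csize.push_back(sz);
      }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return csize[a] > csize[b]; });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[order[r] + 1] = r + 1;
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = newlab[lab[i]];
  out.attr("dim") = dims;
  return out;
}
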