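#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform along one line (lower-envelope
// algorithm of Felzenszwalh & Huttenlocher), with physical sample spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  // envelope only over sites with finite f (empty lines stay at INF)
  static thread_local std::vector<int> sites;
  sites.clear();
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) sites.push_back(q);
  if (sites.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t m = 1; m < sites.size(); ++m) {
    int q = sites[m];
    double s;
    while (true) {
      double pq = q * w, pv = v[k] * w;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double pq = q * w;
    while (z[k + 1] < pq) ++k;
    double pv = v[k] * w;
    d[q] = (pq - pv) * (pq - pv) + f[v[k]];
  }
}

// Squared Euclidean distance (in mm^2) from every voxel to the nearest TRUE
// voxel of `mask`, honouring anisotropic spacing. dims has length 2 or 3.
// Voxels outside the grid are ignored (no virtual background).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int ndim = dims.size();
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  double wx = spacing[0], wy = spacing[1], wz = (ndim == 3) ? spacing[2] : 1.0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, wx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, wy);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // z pass
  if (ndim == 3 && nz > 1) {
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = (R_xlen_t)j * nx + i;
        for (int k = 0; k < nz; ++k) f[k] = out[base + k * nxy];
        dt1d(f, d, v, z, nz, wz);
        for (int k = 0; k < nz; ++k) out[base + k * nxy] = d[k];
      }
  }
  return out;
}

// Connected-component labelling by iterative flood fill.
// full_connectivity: TRUE = 8-neighbour (2-D) / 26-neighbour (3-D);
// FALSE = face connectivity (4 / 6). Labels start at 1 in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   bool full_connectivity) {
  int ndim = dims.size();
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  R_xlen_t n = nxy * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dx, dy, dz;
  for (int ck = (nz > 1 ? -1 : 0); ck <= (nz > 1 ? 1 : 0); ++ck)
    for (int cj = -1; cj <= 1; ++cj)
      for (int ci = -1; ci <= 1; ++ci) {
        if (ci == 0 && cj == 0 && ck == 0) continue;
        int nn = std::abs(ci) + std::abs(cj) + std::abs(ck);
        if (!full_connectivity && nn != 1) continue;
        dx.push_back(ci); dy.push_back(cj); dz.push_back(ck);
      }

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / nxy);
      int rem = (int)(cur - (R_xlen_t)k * nxy);
      int j = rem / nx, i = rem % nx;
      for (size_t m = 0; m < dx.size(); ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
        if (mask[idx] == TRUE && lab[idx] == 0) {
          lab[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  return lab;
}
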