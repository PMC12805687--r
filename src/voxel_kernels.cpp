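// Voxel-grid kernels: exact 3D Euclidean distance transform, connected
// components, marker-controlled watershed, and fixed-radius neighbor counts.
// All grids are column-major (R array layout), dims = (n1, n2, n3).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

typedef long long llong;

static inline llong lin_index(int x, int y, int z, int n1, int n2) {
  return (llong)x + (llong)n1 * ((llong)y + (llong)n2 * (llong)z);
}

// neighbor offsets for 6/18/26 connectivity
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), grid step 1.
// Infinite-valued entries (no feature reachable yet) are skipped: they can
// never anchor a minimizing parabola.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1; // no parabolas in the envelope yet
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break; // z[0] = -inf bounds the pop
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // line holds no finite values
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance (in voxel units) from every
// voxel to the nearest TRUE voxel of `feature`. Isotropic grid.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector feature, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const llong n = (llong)n1 * n2 * n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  // init: 0 on feature voxels, INF elsewhere
  for (llong i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 1
  for (int zc = 0; zc < n3; ++zc)
    for (int y = 0; y < n2; ++y) {
      llong base = lin_index(0, y, zc, n1, n2);
      for (int x = 0; x < n1; ++x) f[x] = out[base + x];
      dt1d(f, d, n1, v, z);
      for (int x = 0; x < n1; ++x) out[base + x] = d[x];
    }
  // pass along dim 2
  for (int zc = 0; zc < n3; ++zc)
    for (int x = 0; x < n1; ++x) {
      llong base = lin_index(x, 0, zc, n1, n2);
      for (int y = 0; y < n2; ++y) f[y] = out[base + (llong)n1 * y];
      dt1d(f, d, n2, v, z);
      for (int y = 0; y < n2; ++y) out[base + (llong)n1 * y] = d[y];
    }
  // pass along dim 3
  const llong stride3 = (llong)n1 * n2;
  for (int y = 0; y < n2; ++y)
    for (int x = 0; x < n1; ++x) {
      llong base = lin_index(x, y, 0, n1, n2);
      for (int zc = 0; zc < n3; ++zc) f[zc] = out[base + stride3 * zc];
      dt1d(f, d, n3, v, z);
      for (int zc = 0; zc < n3; ++zc) out[base + stride3 * zc] = d[zc];
    }
  for (llong i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Connected-component labeling of a binary mask (6/18/26 connectivity).
// Labels are assigned in order of the component's smallest linear index.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const llong n = (llong)n1 * n2 * n3;
  auto off = conn_offsets(connectivity);
  IntegerVector lab(n);
  int next = 0;
  std::vector<llong> stack;
  for (llong i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      llong cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % n1);
      int y = (int)((cur / n1) % n2);
      int zc = (int)(cur / ((llong)n1 * n2));
      for (auto& o : off) {
        int nx = x + o[0], ny = y + o[1], nz = zc + o[2];
        if (nx < 0 || nx >= n1 || ny < 0 || ny >= n2 || nz < 0 || nz >= n3)
          continue;
        llong ni = lin_index(nx, ny, nz, n1, n2);
        if (mask[ni] && lab[ni] == 0) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return lab;
}

// Local maxima of `values` restricted to `mask`: voxel value >= all
// 26-neighbors inside the mask and > 0.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector values, LogicalVector mask,
                               IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const llong n = (llong)n1 * n2 * n3;
  auto off = conn_offsets(26);
  LogicalVector out(n);
  for (llong i = 0; i < n; ++i) {
    if (!mask[i] || values[i] <= 0) { out[i] = false; continue; }
    int x = (int)(i % n1);
    int y = (int)((i / n1) % n2);
    int zc = (int)(i / ((llong)n1 * n2));
    bool ismax = true;
    for (auto& o : off) {
      int nx = x + o[0], ny = y + o[1], nz = zc + o[2];
      if (nx < 0 || nx >= n1 || ny < 0 || ny >= n2 || nz < 0 || nz >= n3)
        continue;
      llong ni = lin_index(nx, ny, nz, n1, n2);
      if (mask[ni] && values[ni] > values[i]) { ismax = false; break; }
    }
    out[i] = ismax;
  }
  return out;
}

// Marker-controlled watershed by priority flooding on `values` (flood from
// high to low; for a split on a negated-distance landscape pass the EDT
// itself). Ties broken by smaller linear index. Growth restricted to mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector values, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims,
                            int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const llong n = (llong)n1 * n2 * n3;
  auto off = conn_offsets(connectivity);
  IntegerVector lab(n);
  typedef std::pair<double, llong> QE; // (value, -index): max-heap
  std::priority_queue<QE> pq;
  for (llong i = 0; i < n; ++i) {
    lab[i] = markers[i];
    if (markers[i] != 0) pq.push(QE(values[i], -i));
  }
  while (!pq.empty()) {
    llong cur = -pq.top().second;
    pq.pop();
    int x = (int)(cur % n1);
    int y = (int)((cur / n1) % n2);
    int zc = (int)(cur / ((llong)n1 * n2));
    for (auto& o : off) {
      int nx = x + o[0], ny = y + o[1], nz = zc + o[2];
      if (nx < 0 || nx >= n1 || ny < 0 || ny >= n2 || nz < 0 || nz >= n3)
        continue;
      llong ni = lin_index(nx, ny, nz, n1, n2);
      if (mask[ni] && lab[ni] == 0) {
        lab[ni] = lab[cur];
        pq.push(QE(values[ni], -ni));
      }
    }
  }
  return lab;
}

// Per-label voxel statistics: count, coordinate sums and second moments
// (0-based voxel indices). Row l-1 holds label l.
// columns: n, sx, sy, sz, sxx, syy, szz, sxy, sxz, syz
// [[Rcpp::export]]
NumericMatrix cpp_label_stats(IntegerVector lab, IntegerVector dims,
                              int nlab) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const llong n = (llong)n1 * n2 * n3;
  NumericMatrix out(nlab, 10);
  for (llong i = 0; i < n; ++i) {
    int l = lab[i];
    if (l <= 0) continue;
    double x = (double)(i % n1);
    double y = (double)((i / n1) % n2);
    double zc = (double)(i / ((llong)n1 * n2));
    int r = l - 1;
    out(r, 0) += 1.0;
    out(r, 1) += x;  out(r, 2) += y;  out(r, 3) += zc;
    out(r, 4) += x * x; out(r, 5) += y * y; out(r, 6) += zc * zc;
    out(r, 7) += x * y; out(r, 8) += x * zc; out(r, 9) += y * zc;
  }
  return out;
}

// Fixed-radius neighbor counts on a point cloud via uniform grid binning.
// Inclusive boundary: j counts as neighbor of i iff ||ci - cj|| <= radius.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors(NumericMatrix coords, double radius) {
  const int n = coords.nrow();
  IntegerVector out(n);
  if (n == 0 || radius <= 0) return out;
  double mins[3], maxs[3];
  for (int d = 0; d < 3; ++d) {
    mins[d] = R_PosInf; maxs[d] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (coords(i, d) < mins[d]) mins[d] = coords(i, d);
      if (coords(i, d) > maxs[d]) maxs[d] = coords(i, d);
    }
  }
  const double cell = radius;
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((maxs[d] - mins[d]) / cell) + 1);
  auto cell_of = [&](int i, int d) {
    int c = (int)std::floor((coords(i, d) - mins[d]) / cell);
    if (c < 0) c = 0;
    if (c >= nc[d]) c = nc[d] - 1;
    return c;
  };
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = cell_of(i, 0); cj[i] = cell_of(i, 1); ck[i] = cell_of(i, 2);
    bins[(size_t)ci[i] + (size_t)nc[0] * (cj[i] + (size_t)nc[1] * ck[i])]
        .push_back(i);
  }
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int bx = ci[i] + dx, by = cj[i] + dy, bz = ck[i] + dz;
          if (bx < 0 || bx >= nc[0] || by < 0 || by >= nc[1] || bz < 0 ||
              bz >= nc[2])
            continue;
          const std::vector<int>& b =
              bins[(size_t)bx + (size_t)nc[0] * (by + (size_t)nc[1] * bz)];
          for (int j : b) {
            if (j == i) continue;
            double s = 0;
            for (int d = 0; d < 3; ++d) {
              double df = coords(i, d) - coords(j, d);
              s += df * df;
            }
            if (s <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}
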