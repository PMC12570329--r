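// Low-level voxel kernels shared by the instance-extraction, morphometry and
// validation modules. All arrays are R arrays with dim = (nz, ny, nx), i.e.
// column-major with z fastest; a voxel (z, y, x) (0-based here) maps to linear
// index z + nz * (y + ny * x). All metric quantities use the physical voxel
// spacing (z, y, x) in micrometres — never raw voxel counts.

#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static inline int lindex(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

struct Offset { int dz, dy, dx; };

static std::vector<Offset> neighbourhood(int connectivity) {
  std::vector<Offset> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6/18/26) by iterative flood fill.
// Components are numbered 1..K in raster scan order of their first voxel;
// the R caller re-orders ids by size with the documented tie-break.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<Offset> off = neighbourhood(connectivity);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = lindex(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (Felzenszwalb-Huttenlocher,
// separable lower envelope of parabolas), with nearest-feature index
// propagation. Returns, for every voxel, the distance (um) from its centre to
// the nearest feature-voxel centre and that feature voxel's 0-based linear
// index (-1 if the feature set is empty).

static void dt1d(std::vector<double> &f, std::vector<int> &id, int n, double w) {
  if (n == 1) return;
  const double INF = std::numeric_limits<double>::infinity();
  int first = -1;
  for (int q = 0; q < n; ++q) if (f[q] != INF) { first = q; break; }
  if (first < 0) return; // whole line infinite
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  std::vector<double> out(n);
  std::vector<int> outid(n);
  int k = 0;
  v[0] = first;
  zb[0] = -INF;
  zb[1] = INF;
  const double w2 = w * w;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      // intersection abscissa (in index units) of parabolas rooted at q and p
      s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
          (2.0 * w2 * (q - p));
      if (s <= zb[k]) --k; // zb[0] = -Inf guarantees k >= 0 here
      else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < (double)q) ++j;
    double d = (double)(q - v[j]) * w;
    out[q] = d * d + f[v[j]];
    outid[q] = id[v[j]];
  }
  f = out;
  id = outid;
}

// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalVector feature, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (feature.size() != n) stop("feature length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d2(n);
  IntegerVector idx(n);
  bool any = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (feature[i]) { d2[i] = 0.0; idx[i] = (int)i; any = true; }
    else { d2[i] = INF; idx[i] = -1; }
  }
  if (!any) {
    std::fill(d2.begin(), d2.end(), INF);
    return List::create(_["dist"] = d2, _["index"] = idx);
  }
  std::vector<double> line;
  std::vector<int> lid;
  // pass along z (stride 1)
  line.resize(nz); lid.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int base = lindex(0, y, x, nz, ny);
      for (int z = 0; z < nz; ++z) { line[z] = d2[base + z]; lid[z] = idx[base + z]; }
      dt1d(line, lid, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) { d2[base + z] = line[z]; idx[base + z] = lid[z]; }
    }
  // pass along y (stride nz)
  line.resize(ny); lid.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      int base = lindex(z, 0, x, nz, ny);
      for (int y = 0; y < ny; ++y) { line[y] = d2[base + (R_xlen_t)y * nz]; lid[y] = idx[base + (R_xlen_t)y * nz]; }
      dt1d(line, lid, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) { d2[base + (R_xlen_t)y * nz] = line[y]; idx[base + (R_xlen_t)y * nz] = lid[y]; }
    }
  // pass along x (stride nz*ny)
  line.resize(nx); lid.resize(nx);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      int base = lindex(z, y, 0, nz, ny);
      for (int x = 0; x < nx; ++x) { line[x] = d2[base + (R_xlen_t)x * sx]; lid[x] = idx[base + (R_xlen_t)x * sx]; }
      dt1d(line, lid, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) { d2[base + (R_xlen_t)x * sx] = line[x]; idx[base + (R_xlen_t)x * sx] = lid[x]; }
    }
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = std::sqrt(d2[i]);
  return List::create(_["dist"] = d2, _["index"] = idx);
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra geodesic distance propagation on the foreground under
// 26-neighbour anisotropic Euclidean step weights. Non-foreground and
// unreachable voxels get +Inf; seed voxels (must be foreground) get 0.
// [[Rcpp::export(name = ".geodesic_cpp")]]
NumericVector geodesic_cpp(LogicalVector fg, LogicalVector seed, IntegerVector dims,
                           NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (fg.size() != n || seed.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<Offset> off = neighbourhood(26);
  std::vector<double> w(off.size());
  for (size_t k = 0; k < off.size(); ++k) {
    double dz = off[k].dz * spacing[0], dy = off[k].dy * spacing[1], dx = off[k].dx * spacing[2];
    w[k] = std::sqrt(dz * dz + dy * dy + dx * dx);
  }
  NumericVector dist(n, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seed[i] && fg[i]) { dist[i] = 0.0; pq.push(QE(0.0, (int)i)); }
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int cur = top.second;
    if (top.first > dist[cur]) continue;
    int x = cur / (nz * ny);
    int rem = cur - x * nz * ny;
    int y = rem / nz;
    int z = rem - y * nz;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = lindex(zz, yy, xx, nz, ny);
      if (!fg[j]) continue;
      double nd = top.first + w[k];
      if (nd < dist[j]) { dist[j] = nd; pq.push(QE(nd, j)); }
    }
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Dijkstra with per-voxel cost multipliers and predecessor tracking, used by
// the TEASAR-style centreline extraction in R: step weight = Euclidean step
// length x mean of the two endpoint cost factors. Returns the (penalized)
// distance field and 0-based predecessor indices (-1 at seeds / unreached).
// [[Rcpp::export(name = ".geodesic_pred_cpp")]]
List geodesic_pred_cpp(LogicalVector fg, LogicalVector seed, IntegerVector dims,
                       NumericVector spacing, NumericVector cost) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (fg.size() != n || seed.size() != n || cost.size() != n)
    stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<Offset> off = neighbourhood(26);
  std::vector<double> w(off.size());
  for (size_t k = 0; k < off.size(); ++k) {
    double dz = off[k].dz * spacing[0], dy = off[k].dy * spacing[1], dx = off[k].dx * spacing[2];
    w[k] = std::sqrt(dz * dz + dy * dy + dx * dx);
  }
  NumericVector dist(n, INF);
  IntegerVector pred(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seed[i] && fg[i]) { dist[i] = 0.0; pq.push(QE(0.0, (int)i)); }
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int cur = top.second;
    if (top.first > dist[cur]) continue;
    int x = cur / (nz * ny);
    int rem = cur - x * nz * ny;
    int y = rem / nz;
    int z = rem - y * nz;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = lindex(zz, yy, xx, nz, ny);
      if (!fg[j]) continue;
      double nd = top.first + w[k] * 0.5 * (cost[cur] + cost[j]);
      if (nd < dist[j]) { dist[j] = nd; pred[j] = cur; pq.push(QE(nd, j)); }
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}
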