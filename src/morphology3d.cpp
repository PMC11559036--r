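#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Volumes are R arrays with dim = c(ny, nx, nz); linear index (0-based) is
// iy + ny * (ix + nx * iz). Connectivity is 26-neighbor throughout.

static inline int lin(int iy, int ix, int iz, int ny, int nx) {
  return iy + ny * (ix + nx * iz);
}

// 26-connected component labeling of a logical mask (BFS with explicit stack).
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int iz = cur / (ny * nx);
      int rem = cur - iz * ny * nx;
      int ix = rem / ny;
      int iy = rem - ix * ny;
      for (int dz = -1; dz <= 1; ++dz) {
        int z = iz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = ix + dx;
          if (x < 0 || x >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (dy == 0 && dx == 0 && dz == 0) continue;
            int y = iy + dy;
            if (y < 0 || y >= ny) continue;
            int nb = lin(y, x, z, ny, nx);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return labels;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher),
// with squared grid spacing w2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from each foreground voxel to
// the nearest background voxel. spacing = voxel size (y, x, z).
// [[Rcpp::export]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = 1e30;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along y
  double w2 = spacing[0] * spacing[0];
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f, d, v, z, ny, w2);
      for (int iy = 0; iy < ny; ++iy) out[lin(iy, ix, iz, ny, nx)] = d[iy];
    }
  // pass along x
  w2 = spacing[1] * spacing[1];
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f, d, v, z, nx, w2);
      for (int ix = 0; ix < nx; ++ix) out[lin(iy, ix, iz, ny, nx)] = d[ix];
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f, d, v, z, nz, w2);
      for (int iz = 0; iz < nz; ++iz) out[lin(iy, ix, iz, ny, nx)] = d[iz];
    }
  return out;
}

// Watershed by descending flooding with prominence merging: voxels of each
// region are processed in order of decreasing f; a voxel joining two basins
// merges them when the lower basin's peak rises less than `h` above the
// connecting saddle (its prominence), otherwise the basins stay distinct.
// Splits clumps whose sub-peaks are separated by deep valleys while leaving
// single cells (whose internal fluctuations are < h) whole. Basins never
// cross region boundaries. Returns compact positive labels inside regions.
// [[Rcpp::export]]
IntegerVector persistence_watershed_3d(NumericVector f, IntegerVector region,
                                       IntegerVector dims, double h) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (f.size() != n || region.size() != n) stop("input lengths do not match dims");
  std::vector<int> order;
  order.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (region[i] > 0) order.push_back((int)i);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return f[a] > f[b]; });
  IntegerVector labels(n, 0);
  std::vector<int> parent(1, 0);      // union-find, 1-based basin ids
  std::vector<double> peak(1, 0.0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<int> nb_basins;
  for (int cur : order) {
    int iz = cur / (ny * nx);
    int rem = cur - iz * ny * nx;
    int ix = rem / ny;
    int iy = rem - ix * ny;
    nb_basins.clear();
    for (int dz = -1; dz <= 1; ++dz) {
      int z = iz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int x = ix + dx;
        if (x < 0 || x >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          if (dy == 0 && dx == 0 && dz == 0) continue;
          int y = iy + dy;
          if (y < 0 || y >= ny) continue;
          int nb = lin(y, x, z, ny, nx);
          if (region[nb] == region[cur] && labels[nb] > 0) {
            int r = find(labels[nb]);
            bool seen = false;
            for (int b : nb_basins) if (b == r) { seen = true; break; }
            if (!seen) nb_basins.push_back(r);
          }
        }
      }
    }
    if (nb_basins.empty()) {
      parent.push_back((int)parent.size());
      peak.push_back(f[cur]);
      labels[cur] = (int)parent.size() - 1;
    } else {
      int best = nb_basins[0];
      for (int b : nb_basins) if (peak[b] > peak[best]) best = b;
      labels[cur] = best;
      for (int b : nb_basins) {
        if (b == best) continue;
        if (peak[b] - f[cur] < h) parent[b] = best;  // insufficient prominence
      }
    }
  }
  // compact final labels
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] == 0) continue;
    int r = find(labels[i]);
    if (remap[r] == 0) remap[r] = ++next;
    labels[i] = remap[r];
  }
  return labels;
}

// Marker-based flooding in order of decreasing priority (distance transform):
// unassigned voxels of each region inherit the label of the first marker
// basin to reach them. region: component id (> 0 foreground); markers: marker
// labels (> 0 at seeds, 0 elsewhere). Flooding never crosses region borders.
// [[Rcpp::export]]
IntegerVector marker_flood_3d(NumericVector priority, IntegerVector markers,
                              IntegerVector region, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (priority.size() != n || markers.size() != n || region.size() != n)
    stop("input lengths do not match dims");
  IntegerVector labels = clone(markers);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node> pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > 0) pq.push(Node(priority[i], (int)i));
  while (!pq.empty()) {
    int cur = pq.top().second;
    pq.pop();
    int iz = cur / (ny * nx);
    int rem = cur - iz * ny * nx;
    int ix = rem / ny;
    int iy = rem - ix * ny;
    for (int dz = -1; dz <= 1; ++dz) {
      int z = iz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int x = ix + dx;
        if (x < 0 || x >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          if (dy == 0 && dx == 0 && dz == 0) continue;
          int y = iy + dy;
          if (y < 0 || y >= ny) continue;
          int nb = lin(y, x, z, ny, nx);
          if (region[nb] == region[cur] && region[nb] > 0 && labels[nb] == 0) {
            labels[nb] = labels[cur];
            pq.push(Node(priority[nb], nb));
          }
        }
      }
    }
  }
  return labels;
}
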