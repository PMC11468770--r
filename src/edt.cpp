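#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
// f: input squared distances at grid positions 0..n-1; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3-D foreground mask: for each
// foreground voxel, the distance (in voxels) to the nearest background voxel;
// 0 on background. Column-major layout, dim = (nx, ny, nz).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e18;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = std::sqrt(d[z]);
    }
  return out;
}

// Gray-weighted geodesic distance transform: cheapest cumulative-intensity
// path from any background voxel, 6-connected (Dijkstra). Edge cost is the
// intensity of the voxel being entered. Background voxels have distance 0.
// [[Rcpp::export(name = ".gwdt3d")]]
NumericVector gwdt3d(NumericVector intensity, LogicalVector mask,
                     IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector dist(n);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) {
      dist[i] = INF;
    } else {
      dist[i] = 0.0;
      pq.push(Node(0.0, i));
    }
  }
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    if (top.first > dist[top.second]) continue;
    R_xlen_t i = top.second;
    int z = (int)(i / nxy);
    int rem = (int)(i - (R_xlen_t)z * nxy);
    int y = rem / nx, x = rem % nx;
    const int dx[6] = {1, -1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, 1, -1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, 1, -1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
      if (!mask[j]) continue;
      double cand = top.first + intensity[j];
      if (cand < dist[j]) {
        dist[j] = cand;
        pq.push(Node(cand, j));
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (dist[i] == INF) dist[i] = 0.0;
  return dist;
}
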