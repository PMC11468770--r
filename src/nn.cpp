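#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact nearest neighbour via a uniform-grid spatial hash. Ties are broken by
// the lower reference-point index (1-based in the returned vector).
// query, ref: n x 3 / m x 3 coordinate matrices.
// [[Rcpp::export(name = ".grid_nn")]]
List grid_nn(NumericMatrix query, NumericMatrix ref, double cell) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  if (m == 0) {
    for (int i = 0; i < n; ++i) {
      idx[i] = NA_INTEGER;
      dist[i] = NA_REAL;
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
  }
  if (cell <= 0.0) cell = 1.0;

  double lo[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = ref(0, d);
    for (int i = 1; i < m; ++i)
      if (ref(i, d) < lo[d]) lo[d] = ref(i, d);
  }
  std::unordered_map<long long, std::vector<int> > grid;
  std::vector<int> cx(m), cy(m), cz(m);
  auto key = [](long long a, long long b, long long c) {
    return ((a & 0x1FFFFFLL) << 42) | ((b & 0x1FFFFFLL) << 21) |
           (c & 0x1FFFFFLL);
  };
  for (int i = 0; i < m; ++i) {
    cx[i] = (int)std::floor((ref(i, 0) - lo[0]) / cell);
    cy[i] = (int)std::floor((ref(i, 1) - lo[1]) / cell);
    cz[i] = (int)std::floor((ref(i, 2) - lo[2]) / cell);
    grid[key(cx[i], cy[i], cz[i])].push_back(i);
  }

  int cmax[3] = {0, 0, 0};
  for (int i = 0; i < m; ++i) {
    if (cx[i] > cmax[0]) cmax[0] = cx[i];
    if (cy[i] > cmax[1]) cmax[1] = cy[i];
    if (cz[i] > cmax[2]) cmax[2] = cz[i];
  }

  for (int q = 0; q < n; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int gx = (int)std::floor((px - lo[0]) / cell);
    int gy = (int)std::floor((py - lo[1]) / cell);
    int gz = (int)std::floor((pz - lo[2]) / cell);
    // beyond this ring no occupied cell can exist
    int ring_cap = 0;
    ring_cap = std::max(ring_cap, std::max(std::abs(gx), std::abs(gx - cmax[0])));
    ring_cap = std::max(ring_cap, std::max(std::abs(gy), std::abs(gy - cmax[1])));
    ring_cap = std::max(ring_cap, std::max(std::abs(gz), std::abs(gz - cmax[2])));
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    for (int ring = 0;; ++ring) {
      // smallest possible distance from the query to any cell in this ring
      double ring_min = (ring == 0) ? 0.0 : (ring - 1) * cell;
      if (besti >= 0 && ring_min * ring_min > best) break;
      // enumerate only the shell of Chebyshev radius `ring`
      auto visit = [&](int ax, int ay, int az) {
        auto it = grid.find(key(ax, ay, az));
        if (it == grid.end()) return;
        for (int i : it->second) {
          double dx = ref(i, 0) - px, dy = ref(i, 1) - py, dz = ref(i, 2) - pz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best || (d2 == best && i < besti)) {
            best = d2;
            besti = i;
          }
        }
      };
      for (int ax = gx - ring; ax <= gx + ring; ++ax)
        for (int ay = gy - ring; ay <= gy + ring; ++ay) {
          if (std::abs(ax - gx) == ring || std::abs(ay - gy) == ring) {
            for (int az = gz - ring; az <= gz + ring; ++az) visit(ax, ay, az);
          } else if (ring > 0) {
            visit(ax, ay, gz - ring);
            visit(ax, ay, gz + ring);
          } else {
            visit(ax, ay, gz);
          }
        }
      if (ring >= ring_cap && besti >= 0) break; // every occupied cell seen
      if (ring > ring_cap + 1) {
        // unreachable in principle; fall back to a full scan
        for (int i = 0; i < m; ++i) {
          double dx = ref(i, 0) - px, dy = ref(i, 1) - py, dz = ref(i, 2) - pz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best || (d2 == best && i < besti)) {
            best = d2;
            besti = i;
          }
        }
        break;
      }
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
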