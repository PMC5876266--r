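#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Linear index <-> (i,j,k) helpers for column-major 3-D arrays, 0-based.
static inline void unravel(int64_t idx, int nx, int ny, int &i, int &j, int &k) {
  i = (int)(idx % nx);
  j = (int)((idx / nx) % ny);
  k = (int)(idx / ((int64_t)nx * ny));
}

// Dijkstra shortest path on the 26-connected voxel grid.
// Edge weight = mean(cost[u], cost[v]) * physical step length (mm).
// Non-finite cost voxels are impassable. Ties in the priority queue are
// broken by the smaller lexicographic (i,j,k) voxel index so the pop order,
// and hence the predecessor tree, is deterministic.
// [[Rcpp::export]]
IntegerVector dijkstra_grid_cpp(NumericVector cost, IntegerVector dims,
                                NumericVector spacing, int src, int dst) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  if (src < 0 || src >= n || dst < 0 || dst >= n)
    stop("source or target voxel outside the grid");
  if (!R_finite(cost[src]) || !R_finite(cost[dst]))
    stop("source or target voxel has non-finite cost");

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> prev(n, -1);
  std::vector<char> done(n, 0);

  struct Node { double d; int i, j, k; int64_t idx; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.d != b.d) return a.d > b.d;
      if (a.i != b.i) return a.i > b.i;
      if (a.j != b.j) return a.j > b.j;
      return a.k > b.k;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;

  int si, sj, sk; unravel(src, nx, ny, si, sj, sk);
  dist[src] = 0.0;
  pq.push({0.0, si, sj, sk, src});

  // precompute the 26 neighbour offsets and their physical lengths
  int di[26], dj[26], dk[26]; double len[26]; int m = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        di[m] = a; dj[m] = b; dk[m] = c;
        double dx = a * spacing[0], dy = b * spacing[1], dz = c * spacing[2];
        len[m] = std::sqrt(dx * dx + dy * dy + dz * dz);
        ++m;
      }

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int64_t u = nd.idx;
    if (done[u]) continue;
    done[u] = 1;
    if (u == dst) break;
    double cu = cost[u];
    for (int t = 0; t < 26; ++t) {
      int vi = nd.i + di[t], vj = nd.j + dj[t], vk = nd.k + dk[t];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      int64_t v = (int64_t)vi + (int64_t)nx * vj + (int64_t)nx * ny * vk;
      if (done[v]) continue;
      double cv = cost[v];
      if (!R_finite(cv)) continue;
      double nd2 = dist[u] + 0.5 * (cu + cv) * len[t];
      if (nd2 < dist[v]) {
        dist[v] = nd2;
        prev[v] = (int)u;
        pq.push({nd2, vi, vj, vk, v});
      }
    }
  }

  if (!done[dst]) return IntegerVector(0); // unreachable; caller raises the error

  std::vector<int> path;
  for (int cur = dst; cur != -1; cur = prev[cur]) {
    path.push_back(cur);
    if (cur == src) break;
  }
  std::reverse(path.begin(), path.end());
  IntegerVector out(path.size());
  for (size_t t = 0; t < path.size(); ++t) out[t] = path[t];
  out.attr("total_cost") = dist[dst];
  return out;
}

// Connected-component labeling of a binary 3-D mask (pass nz = 1 for 2-D).
// connectivity: 6 (faces) or 26 (faces+edges+corners); for 2-D these act as
// 4- and 8-connectivity. Returns integer labels, 0 = background, components
// numbered in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t u = stack.back(); stack.pop_back();
      int ui, uj, uk; unravel(u, nx, ny, ui, uj, uk);
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            int nb = std::abs(a) + std::abs(b) + std::abs(c);
            if (connectivity == 6 && nb != 1) continue;
            int vi = ui + a, vj = uj + b, vk = uk + c;
            if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
              continue;
            int64_t v = (int64_t)vi + (int64_t)nx * vj + (int64_t)nx * ny * vk;
            if (mask[v] && lab[v] == 0) { lab[v] = next; stack.push_back(v); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Binary dilation (op = 1) or erosion (op = 0) with a 3x3x3 box element.
// [[Rcpp::export]]
LogicalVector morph3_cpp(LogicalVector mask, IntegerVector dims, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  LogicalVector out(n);
  for (int64_t s = 0; s < n; ++s) {
    int i, j, k; unravel(s, nx, ny, i, j, k);
    bool acc = (op == 0); // erosion starts true (AND), dilation false (OR)
    for (int a = -1; a <= 1 && (op == 1 ? !acc : acc); ++a)
      for (int b = -1; b <= 1 && (op == 1 ? !acc : acc); ++b)
        for (int c = -1; c <= 1 && (op == 1 ? !acc : acc); ++c) {
          int vi = i + a, vj = j + b, vk = k + c;
          bool val;
          if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
            val = false; // outside the grid counts as background
          else
            val = mask[(int64_t)vi + (int64_t)nx * vj + (int64_t)nx * ny * vk];
          if (op == 1) acc = acc || val; else acc = acc && val;
        }
    out[s] = acc;
  }
  return out;
}
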