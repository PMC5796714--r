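#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cstdint>

using namespace Rcpp;

// Exact minimiser of linear-penalty (d = 1) agony.
//
// The LP  min sum_e max(0, r(u) - r(v) + 1)  over node potentials r has a
// totally unimodular constraint matrix, so its integral optimum is the agony
// optimum. Its dual is a maximum circulation with unit capacities (the
// largest Eulerian subgraph). We solve the dual as a min-cost flow problem:
// every edge (u,v) gets cost -1 and is saturated up front, and the resulting
// node imbalances are repaired at minimum cost by successive shortest paths
// with Johnson potentials. Optimal ranks are recovered from shortest-path
// distances in the residual network (no negative cycle exists at optimality).

namespace {

struct Arc {
  int to;
  int cap;
  int cost;
  int next;
};

const int64_t INF = std::numeric_limits<int64_t>::max() / 4;

} // namespace

// [[Rcpp::export]]
List agony_flow_cpp(IntegerVector src, IntegerVector dst, int n) {
  const int m = src.size();
  std::vector<int> head(n, -1);
  std::vector<Arc> arcs;
  arcs.reserve(2 * static_cast<size_t>(m));
  std::vector<int64_t> excess(n, 0);

  auto add_arc = [&](int u, int v, int cap, int cost) {
    arcs.push_back(Arc{v, cap, cost, head[u]});
    head[u] = static_cast<int>(arcs.size()) - 1;
  };

  for (int e = 0; e < m; ++e) {
    int u = src[e], v = dst[e];
    if (u < 0 || u >= n || v < 0 || v >= n) stop("edge endpoint out of range");
    // edge already saturated: forward residual 0, reverse residual 1 (cost +1)
    add_arc(u, v, 0, -1);
    add_arc(v, u, 1, +1);
    excess[v] += 1;
    excess[u] -= 1;
  }

  std::vector<int64_t> pi(n, 0), dist(n);
  std::vector<int> prev_arc(n, -1);
  std::vector<char> done(n, 0);

  typedef std::pair<int64_t, int> QItem;

  int64_t remaining = 0;
  for (int v = 0; v < n; ++v)
    if (excess[v] > 0) remaining += excess[v];

  while (remaining > 0) {
    std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    for (int v = 0; v < n; ++v) {
      if (excess[v] > 0) {
        dist[v] = 0;
        pq.push(QItem(0, v));
      }
    }
    int target = -1;
    int64_t dt = 0;
    while (!pq.empty()) {
      QItem top = pq.top();
      pq.pop();
      int u = top.second;
      if (done[u]) continue;
      done[u] = 1;
      if (excess[u] < 0) {
        target = u;
        dt = top.first;
        break;
      }
      for (int a = head[u]; a != -1; a = arcs[a].next) {
        if (arcs[a].cap <= 0) continue;
        int v = arcs[a].to;
        if (done[v]) continue;
        int64_t nd = top.first + arcs[a].cost + pi[u] - pi[v];
        if (nd < dist[v]) {
          dist[v] = nd;
          prev_arc[v] = a;
          pq.push(QItem(nd, v));
        }
      }
    }
    if (target < 0)
      stop("internal error: unmatched excess in circulation solver");
    for (int v = 0; v < n; ++v)
      pi[v] += std::min(dist[v], dt);
    // push one unit back along the shortest path
    int v = target;
    while (excess[v] <= 0) {
      int a = prev_arc[v];
      arcs[a].cap -= 1;
      arcs[a ^ 1].cap += 1;
      v = arcs[a ^ 1].to;
    }
    excess[v] -= 1;
    excess[target] += 1;
    remaining -= 1;
  }

  // ranks from shortest distances in the residual graph (virtual source at 0
  // to every node); Bellman-Ford queue relaxation, safe because the optimal
  // circulation admits no negative residual cycle.
  std::vector<int64_t> d0(n, 0);
  std::vector<char> inq(n, 1);
  std::queue<int> bf;
  for (int v = 0; v < n; ++v) bf.push(v);
  int64_t rounds = 0;
  const int64_t max_relax = static_cast<int64_t>(n + 1) * (2 * m + n + 1) * 4;
  while (!bf.empty()) {
    if (++rounds > max_relax)
      stop("internal error: negative cycle in residual network");
    int u = bf.front();
    bf.pop();
    inq[u] = 0;
    for (int a = head[u]; a != -1; a = arcs[a].next) {
      if (arcs[a].cap <= 0) continue;
      int v = arcs[a].to;
      if (d0[u] + arcs[a].cost < d0[v]) {
        d0[v] = d0[u] + arcs[a].cost;
        if (!inq[v]) {
          inq[v] = 1;
          bf.push(v);
        }
      }
    }
  }

  int64_t dmax = 0;
  for (int v = 0; v < n; ++v) dmax = std::max(dmax, -d0[v]);
  IntegerVector rank(n);
  int64_t dmin = INF;
  for (int v = 0; v < n; ++v) dmin = std::min(dmin, -d0[v]);
  if (n == 0) dmin = 0;
  for (int v = 0; v < n; ++v)
    rank[v] = static_cast<int>(-d0[v] - dmin + 1);

  // circulation value (optimal agony) = units still on the original edges
  double flow_value = 0;
  for (int e = 0; e < m; ++e) flow_value += arcs[2 * e + 1].cap;

  double agony = 0;
  for (int e = 0; e < m; ++e) {
    int diff = rank[src[e]] - rank[dst[e]] + 1;
    if (diff > 0) agony += diff;
  }

  return List::create(_["rank"] = rank, _["agony"] = agony,
                      _["flow_value"] = flow_value);
}
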