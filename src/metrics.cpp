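#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// adjacency matrix (0/1) -> adjacency lists
static std::vector<std::vector<int>> adj_list(const IntegerMatrix &a) {
  int n = a.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && a(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// BFS distances from source; -1 marks unreachable
static void bfs(const std::vector<std::vector<int>> &adj, int s,
                std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  std::queue<int> q;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v : adj[u])
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
  }
}

// efficiency of the graph given by adjacency lists restricted to all nodes:
// mean over ordered pairs of 1/d_ij with 1/inf = 0
static double efficiency(const std::vector<std::vector<int>> &adj) {
  int n = (int)adj.size();
  if (n < 2) return 0.0;
  std::vector<int> dist(n);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) s += 1.0 / dist[j];
  }
  return s / ((double)n * (n - 1));
}

// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(IntegerMatrix a) {
  int n = a.nrow();
  auto adj = adj_list(a);
  NumericMatrix d(n, n);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist);
    for (int j = 0; j < n; ++j)
      d(i, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return d;
}

// [[Rcpp::export]]
double cpp_global_efficiency(IntegerMatrix a) {
  return efficiency(adj_list(a));
}

// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix a) {
  int n = a.nrow();
  if (n == 0) return 0.0;
  auto adj = adj_list(a);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &nb = adj[i];
    int m = (int)nb.size();
    if (m < 2) continue;             // E(G_i) = 0 for < 2 neighbors
    // induced subgraph on the neighbors of i
    std::vector<std::vector<int>> sub(m);
    for (int u = 0; u < m; ++u)
      for (int v = 0; v < m; ++v)
        if (u != v && a(nb[u], nb[v]) != 0) sub[u].push_back(v);
    total += efficiency(sub);
  }
  return total / n;
}
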