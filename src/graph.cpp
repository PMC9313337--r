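// Hot-path graph primitives: incremental acyclic edge insertion and a
// Kahn-peeling acyclicity test over index vectors. Node ids are 1-based
// indices supplied by the R side.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// DFS: is `to` reachable from `from` in adj?
bool dfs_reaches(const std::vector<std::vector<int>>& adj, int from, int to,
                 std::vector<int>& seen, int stamp) {
  if (from == to) return true;
  std::vector<int> stack{from};
  seen[from] = stamp;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w : adj[v]) {
      if (w == to) return true;
      if (seen[w] != stamp) {
        seen[w] = stamp;
        stack.push_back(w);
      }
    }
  }
  return false;
}

}  // namespace

// Insert edges in the given order, skipping any that would close a cycle.
// Returns a logical keep vector aligned with the input order.
// [[Rcpp::export]]
LogicalVector greedy_insert_cpp(IntegerVector src, IntegerVector tgt,
                                int n_nodes) {
  int m = src.size();
  std::vector<std::vector<int>> adj(n_nodes + 1);
  std::vector<int> seen(n_nodes + 1, 0);
  LogicalVector keep(m);
  for (int e = 0; e < m; ++e) {
    int u = src[e], v = tgt[e];
    if (u == v) {
      keep[e] = false;
      continue;
    }
    if (!dfs_reaches(adj, v, u, seen, e + 1)) {
      adj[u].push_back(v);
      keep[e] = true;
    } else {
      keep[e] = false;
    }
  }
  return keep;
}

// Kahn peeling acyclicity test on the edges where alive[e] is TRUE.
// [[Rcpp::export]]
bool edges_acyclic_cpp(IntegerVector src, IntegerVector tgt,
                       LogicalVector alive, int n_nodes) {
  int m = src.size();
  std::vector<int> indeg(n_nodes + 1, 0), outcount(n_nodes + 1, 0);
  std::vector<std::vector<int>> out_edges(n_nodes + 1);
  int n_alive = 0;
  for (int e = 0; e < m; ++e) {
    if (!alive[e]) continue;
    if (src[e] == tgt[e]) return false;
    ++n_alive;
    ++indeg[tgt[e]];
    out_edges[src[e]].push_back(tgt[e]);
  }
  if (n_alive == 0) return true;
  std::vector<int> stack;
  for (int v = 1; v <= n_nodes; ++v)
    if (indeg[v] == 0) stack.push_back(v);
  int peeled = 0;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w : out_edges[v]) {
      ++peeled;
      if (--indeg[w] == 0) stack.push_back(w);
    }
  }
  return peeled == n_alive;
}
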