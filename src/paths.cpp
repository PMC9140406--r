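#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Enumerate all simple paths of exactly `len` edges from `start` to `target`
// by depth-first search, never traversing the direct start-target edge.
// Nodes use combined 1-based indexing (U nodes 1..n_u, V nodes n_u+1..n_u+n_v);
// `adj` is a 0-based-unfriendly R adjacency list (1-based neighbour vectors).
//
// The search is pruned with exact BFS distances to `target` computed on the
// graph minus the forbidden edge: a partial path is extended only while the
// remaining edge budget can still reach the target (bipartite parity makes
// the distance bound tight, no separate parity test is needed).
// [[Rcpp::export(name = ".cpp_connecting_paths")]]
List cpp_connecting_paths(List adj, int start, int target, int len, int cap) {
  int n = adj.size();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
    for (size_t j = 0; j < nb[i].size(); ++j) nb[i][j] -= 1; // 0-based
  }
  int s = start - 1, t = target - 1;

  // BFS distances to target, excluding the direct s-t edge
  std::vector<int> dist(n, -1);
  std::queue<int> q;
  dist[t] = 0; q.push(t);
  while (!q.empty()) {
    int x = q.front(); q.pop();
    for (int y : nb[x]) {
      if ((x == s && y == t) || (x == t && y == s)) continue;
      if (dist[y] < 0) { dist[y] = dist[x] + 1; q.push(y); }
    }
  }

  std::vector<int> path;
  path.reserve(len + 1);
  std::vector<bool> visited(n, false);
  std::vector<IntegerVector> out;
  bool capped = false;

  // iterative DFS: frame = (node, next-neighbour cursor)
  std::vector< std::pair<int, size_t> > stack;
  path.push_back(s); visited[s] = true;
  stack.push_back(std::make_pair(s, (size_t)0));
  while (!stack.empty()) {
    int node = stack.back().first;
    size_t &cur = stack.back().second;
    int remaining = len - ((int)path.size() - 1);
    bool descended = false;
    while (cur < nb[node].size()) {
      int nxt = nb[node][cur++];
      if ((node == s && nxt == t) || (node == t && nxt == s)) continue;
      if (visited[nxt]) continue;
      if (remaining == 1) {
        if (nxt == t) {
          if ((int)out.size() >= cap) { capped = true; break; }
          IntegerVector p(path.size() + 1);
          for (size_t i = 0; i < path.size(); ++i) p[i] = path[i] + 1;
          p[path.size()] = t + 1;
          out.push_back(p);
        }
        continue;
      }
      if (nxt == t) continue;                 // simple path: cannot revisit t later
      if (dist[nxt] < 0 || dist[nxt] > remaining - 1) continue;
      path.push_back(nxt); visited[nxt] = true;
      stack.push_back(std::make_pair(nxt, (size_t)0));
      descended = true;
      break;
    }
    if (capped) break;
    if (!descended && !stack.empty() && stack.back().first == node && cur >= nb[node].size()) {
      visited[node] = false;
      path.pop_back();
      stack.pop_back();
    }
  }

  List paths(out.size());
  for (size_t i = 0; i < out.size(); ++i) paths[i] = out[i];
  return List::create(_["paths"] = paths, _["capped"] = capped);
}
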