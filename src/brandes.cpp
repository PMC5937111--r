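#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Single-sweep accumulation betweenness for an unweighted undirected
// simple graph: one BFS per source with geodesic counting, followed by
// reverse-order dependency accumulation. O(VE) total. Each unordered
// (s, t) pair contributes twice (once per endpoint as source), so the
// accumulated totals are halved before returning.
// [[Rcpp::export(name = ".brandes_raw")]]
NumericVector brandes_raw(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj(n);
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  std::vector<double> bc(n, 0.0);
  std::vector<int> dist(n), order;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();

    std::queue<int> q;
    dist[s] = 0; sigma[s] = 1.0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (int w : adj[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = bc[v] / 2.0;
  return out;
}
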