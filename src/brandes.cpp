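// Brandes' betweenness accumulation for undirected graphs, computing node and
// edge betweenness in one sweep. Unweighted mode uses BFS; weighted mode runs
// Dijkstra over supplied edge lengths (the package passes 1/weight so heavy
// co-occurrence means short distance). Equal-length shortest-path ties are
// detected with a 1e-12 relative tolerance. Raw scores count each unordered
// pair once: node scores exclude endpoints, edge scores include them.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List brandes_cpp(int n, IntegerVector ei, IntegerVector ej,
                 NumericVector len, bool weighted) {
  const int m = ei.size();
  // CSR adjacency with edge ids
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[ei[e]]++; deg[ej[e]]++; }
  std::vector<int> off(n + 1, 0);
  for (int v = 0; v < n; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * m), aedge(2 * m), pos(n, 0);
  for (int e = 0; e < m; ++e) {
    int u = ei[e], v = ej[e];
    adj[off[u] + pos[u]] = v; aedge[off[u] + pos[u]] = e; pos[u]++;
    adj[off[v] + pos[v]] = u; aedge[off[v] + pos[v]] = e; pos[v]++;
  }

  NumericVector node_bc(n), edge_bc(m);
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<int> order; order.reserve(n);
  std::vector<std::vector<std::pair<int, int> > > pred(n);

  for (int s = 0; s < n; ++s) {
    for (int v = 0; v < n; ++v) {
      dist[v] = -1.0; sigma[v] = 0.0; delta[v] = 0.0; pred[v].clear();
    }
    order.clear();
    sigma[s] = 1.0; dist[s] = 0.0;

    if (!weighted) {
      std::queue<int> q; q.push(s);
      while (!q.empty()) {
        int v = q.front(); q.pop();
        order.push_back(v);
        for (int k = off[v]; k < off[v + 1]; ++k) {
          int w = adj[k], e = aedge[k];
          if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
          if (dist[w] == dist[v] + 1) {
            sigma[w] += sigma[v];
            pred[w].push_back(std::make_pair(v, e));
          }
        }
      }
    } else {
      typedef std::pair<double, int> Qe;
      std::priority_queue<Qe, std::vector<Qe>, std::greater<Qe> > pq;
      std::vector<bool> done(n, false);
      pq.push(std::make_pair(0.0, s));
      while (!pq.empty()) {
        double d = pq.top().first; int v = pq.top().second; pq.pop();
        if (done[v]) continue;
        done[v] = true;
        order.push_back(v);
        for (int k = off[v]; k < off[v + 1]; ++k) {
          int w = adj[k], e = aedge[k];
          if (done[w]) continue;
          double alt = d + len[e];
          double eps = 1e-12 * std::max(1.0, std::fabs(alt));
          if (dist[w] < 0 || alt < dist[w] - eps) {
            dist[w] = alt;
            sigma[w] = sigma[v];
            pred[w].clear();
            pred[w].push_back(std::make_pair(v, e));
            pq.push(std::make_pair(alt, w));
          } else if (std::fabs(alt - dist[w]) <= eps) {
            sigma[w] += sigma[v];
            pred[w].push_back(std::make_pair(v, e));
          }
        }
      }
    }

    for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
      int w = order[idx];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k].first, e = pred[w][k].second;
        double c = sigma[v] / sigma[w] * (1.0 + delta[w]);
        edge_bc[e] += c;
        delta[v] += c;
      }
      if (w != s) node_bc[w] += delta[w];
    }
  }
  for (int v = 0; v < n; ++v) node_bc[v] /= 2.0;
  for (int e = 0; e < m; ++e) edge_bc[e] /= 2.0;
  return List::create(Named("node") = node_bc, Named("edge") = edge_bc);
}
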