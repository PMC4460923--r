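#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>

using namespace Rcpp;

// Single-pass BFS accumulation of shortest-path statistics for an
// undirected, unweighted graph (Brandes' scheme, plus the stress variant:
// the pair dependency for stress counts whole geodesics through a vertex
// instead of path fractions).
//
// edges: 2-column integer matrix, 0-based vertex ids
// n: number of vertices
//
// Returns betweenness and stress with every unordered (s,t) pair counted
// once, eccentricity within each component, the sum of finite distances
// from each vertex, and the number of vertices reachable from each vertex
// (self excluded).
// [[Rcpp::export(name = ".cpp_sp_stats")]]
List cpp_sp_stats(IntegerMatrix edges, int n) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    adj[u].push_back(v);
    adj[v].push_back(u);
  }

  NumericVector betweenness(n), stress(n), sum_dist(n);
  IntegerVector eccentricity(n), reach(n);

  std::vector<int> dist(n), order;
  std::vector<double> sigma(n), delta(n), phi(n);
  std::vector<std::vector<int>> pred(n);
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();

    std::queue<int> q;
    dist[s] = 0;
    sigma[s] = 1.0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      order.push_back(v);
      for (int w : adj[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }

    int ecc = 0;
    double sd = 0.0;
    for (int v : order) {
      if (dist[v] > ecc) ecc = dist[v];
      sd += dist[v];
    }
    eccentricity[s] = ecc;
    sum_dist[s] = sd;
    reach[s] = static_cast<int>(order.size()) - 1;

    // reverse BFS order: accumulate pair dependencies
    for (int i = static_cast<int>(order.size()) - 1; i >= 0; --i) {
      int w = order[i];
      for (int v : pred[w]) {
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
        phi[v] += 1.0 + phi[w];
      }
      if (w != s) {
        betweenness[w] += delta[w];
        stress[w] += sigma[w] * phi[w];
      }
    }
  }

  // each unordered pair was seen from both endpoints
  for (int v = 0; v < n; ++v) {
    betweenness[v] /= 2.0;
    stress[v] /= 2.0;
  }

  return List::create(_["betweenness"] = betweenness, _["stress"] = stress,
                      _["eccentricity"] = eccentricity,
                      _["sum_dist"] = sum_dist, _["reach"] = reach);
}
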