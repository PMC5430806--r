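#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted geodesic engine for small dense contact networks.
//
// Edge weights are interaction rates (affinities); geodesic measures need
// costs, so edge length = 1/weight. One Dijkstra per source (O(n^2) node
// selection -- camps have at most a few dozen members, so a heap would be
// noise), with Brandes' dependency accumulation for betweenness. Geodesic
// ties are detected with a relative tolerance so that equal-length paths
// arising from exactly representable weights are credited fractionally.
//
// Returns unnormalized betweenness (unordered pairs counted once, endpoints
// excluded) and the full shortest-path distance matrix (Inf when
// unreachable), from which closeness is computed on the R side.

// [[Rcpp::export(name = ".graph_geodesics")]]
List graph_geodesics(NumericMatrix W) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("adjacency matrix must be square");
  NumericMatrix D(n, n);
  NumericVector btw(n);
  std::fill(D.begin(), D.end(), R_PosInf);
  const double eps = 1e-12;

  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<char> done(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order;
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    for (int v = 0; v < n; ++v) {
      dist[v] = R_PosInf;
      sigma[v] = 0.0;
      delta[v] = 0.0;
      done[v] = 0;
      pred[v].clear();
    }
    order.clear();
    dist[s] = 0.0;
    sigma[s] = 1.0;

    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      order.push_back(u);
      for (int v = 0; v < n; ++v) {
        if (done[v]) continue;
        double w = W(u, v);
        if (!(w > 0.0)) continue;
        double nd = dist[u] + 1.0 / w;
        double tol = eps * (std::fabs(nd) + std::fabs(dist[v] == R_PosInf ? 0.0 : dist[v]) + 1.0);
        if (nd < dist[v] - tol) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
        } else if (std::fabs(nd - dist[v]) <= tol) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }

    for (int i = (int) order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) btw[w] += delta[w];
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
  }

  // each unordered pair was visited from both endpoints
  for (int v = 0; v < n; ++v) btw[v] /= 2.0;

  return List::create(_["betweenness"] = btw, _["dist"] = D);
}
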