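// Shortest-path kernels for weighted undirected connectomes.
//
// Edge lengths are supplied by the R side (1/w or -log w); absent edges
// are encoded as R_PosInf. All routines assume a symmetric length matrix
// with a zero diagonal.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// In-place Floyd-Warshall on a column-major n x n buffer.
static void fw_inplace(double *d, int n) {
  for (int c = 0; c < n; ++c) {
    const double *col_c = d + (size_t)n * c;
    for (int b = 0; b < n; ++b) {
      double dcb = d[c + (size_t)n * b];
      if (!R_finite(dcb)) continue;
      double *col_b = d + (size_t)n * b;
      for (int a = 0; a < n; ++a) {
        double via = col_c[a] + dcb;
        if (via < col_b[a]) col_b[a] = via;
      }
    }
  }
}

// Floyd-Warshall all-pairs shortest paths on a length matrix.
// [[Rcpp::export(name = ".fw_distances")]]
NumericMatrix fw_distances_cpp(NumericMatrix L) {
  int n = L.nrow();
  NumericMatrix D(clone(L));
  fw_inplace(REAL(D), n);
  return D;
}

// Nodal local efficiency: mean inverse shortest-path length within each
// node's neighbour-induced subgraph (original weights; lengths given).
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
NumericVector local_efficiency_cpp(NumericMatrix W, NumericMatrix L) {
  int n = W.nrow();
  NumericVector eff(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (W(i, j) > 0) nb.push_back(j);
    }
    int k = (int)nb.size();
    if (k < 2) { eff[i] = 0.0; continue; }
    // distances within the induced subgraph
    std::vector<double> D((size_t)k * k);
    const double *Lp = REAL(L);
    int nL = L.nrow();
    for (int b = 0; b < k; ++b) {
      const double *colL = Lp + (size_t)nL * nb[b];
      for (int a = 0; a < k; ++a) {
        D[a + (size_t)k * b] = (a == b) ? 0.0 : colL[nb[a]];
      }
    }
    fw_inplace(D.data(), k);
    double tot = 0.0;
    for (size_t idx = 0; idx < D.size(); ++idx) {
      double dv = D[idx];
      if (dv > 0.0 && R_finite(dv)) tot += 1.0 / dv;
    }
    eff[i] = tot / ((double)k * (k - 1));
  }
  return eff;
}

// Brandes betweenness on weighted undirected graphs, counting tied
// shortest paths with multiplicity. Relative tolerance matches the pure-R
// reference implementation used by the test oracles.
// [[Rcpp::export(name = ".betweenness_cpp")]]
NumericVector betweenness_cpp(NumericMatrix W, NumericMatrix L) {
  int n = W.nrow();
  NumericVector bc(n);
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (W(i, j) > 0) adj[i].push_back(j);
    }
  }
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> visited(n);
  std::vector<int> order;
  std::vector<std::vector<int> > preds(n);
  order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(visited.begin(), visited.end(), false);
    for (int i = 0; i < n; ++i) preds[i].clear();
    order.clear();
    dist[s] = 0.0; sigma[s] = 1.0;
    while (true) {
      int u = -1; double best = R_PosInf;
      for (int i = 0; i < n; ++i) {
        if (!visited[i] && dist[i] < best) { best = dist[i]; u = i; }
      }
      if (u < 0) break;
      visited[u] = true;
      order.push_back(u);
      double du = dist[u];
      for (size_t a = 0; a < adj[u].size(); ++a) {
        int v = adj[u][a];
        if (visited[v]) continue;
        double nd = du + L(u, v);
        double tol = 1e-10 * (1.0 + std::abs(nd));
        if (nd < dist[v] - tol) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          preds[v].assign(1, u);
        } else if (std::abs(nd - dist[v]) <= tol) {
          sigma[v] += sigma[u];
          preds[v].push_back(u);
        }
      }
    }
    for (int t = (int)order.size() - 1; t >= 0; --t) {
      int u = order[t];
      for (size_t a = 0; a < preds[u].size(); ++a) {
        int p = preds[u][a];
        delta[p] += sigma[p] / sigma[u] * (1.0 + delta[u]);
      }
      if (u != s) bc[u] += delta[u];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // undirected double count
  return bc;
}
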