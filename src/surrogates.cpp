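// Fast kernel for the surrogate random-network ensemble on small dense
// graphs: weight permutation on a fixed topology, with Onnela weighted
// clustering and Floyd-Warshall characteristic path length per surrogate.
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static double onnela_clustering(const std::vector<double>& W, int n) {
  double mx = 0.0;
  for (double v : W) if (v > mx) mx = v;
  if (mx <= 0.0) return 0.0;
  std::vector<double> Wc(n * n);
  for (int i = 0; i < n * n; ++i) Wc[i] = std::cbrt(W[i] / mx);
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) if (W[i * n + j] > 0.0) ++k;
    if (k < 2) continue;
    double num = 0.0;
    for (int j = 0; j < n; ++j) {
      if (Wc[i * n + j] == 0.0) continue;
      for (int h = 0; h < n; ++h)
        num += Wc[i * n + j] * Wc[j * n + h] * Wc[h * n + i];
    }
    csum += num / (static_cast<double>(k) * (k - 1));
  }
  return csum / n;
}

static double char_path_length(const std::vector<double>& W, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      D[i * n + j] = (i == j) ? 0.0 : (W[i * n + j] > 0.0 ? 1.0 / W[i * n + j]
                                                          : INF);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double dik = D[i * n + k];
      if (!std::isfinite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + D[k * n + j];
        if (alt < D[i * n + j]) D[i * n + j] = alt;
      }
    }
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) s += D[i * n + j];
  return s / (static_cast<double>(n) * (n - 1));
}

// Surrogate ensemble on a fixed topology: the original edge-weight multiset
// is randomly reassigned to `edges` (0-based, i < j) for each surrogate.
// [[Rcpp::export(name = ".surrogate_metrics_perm")]]
List surrogate_metrics_perm(NumericMatrix W, IntegerMatrix edges,
                            int n_surrogates) {
  int n = W.nrow();
  int m = edges.nrow();
  std::vector<double> wts(m);
  for (int e = 0; e < m; ++e) wts[e] = W(edges(e, 0), edges(e, 1));
  NumericVector Cs(n_surrogates), Ls(n_surrogates);
  std::vector<double> Ws(n * n);
  std::vector<int> perm(m);
  for (int s = 0; s < n_surrogates; ++s) {
    for (int e = 0; e < m; ++e) perm[e] = e;
    for (int e = m - 1; e > 0; --e) {  // Fisher-Yates on R's RNG stream
      int j = static_cast<int>(unif_rand() * (e + 1));
      if (j > e) j = e;
      std::swap(perm[e], perm[j]);
    }
    std::fill(Ws.begin(), Ws.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      double v = wts[perm[e]];
      int i = edges(e, 0), j = edges(e, 1);
      Ws[i * n + j] = v;
      Ws[j * n + i] = v;
    }
    Cs[s] = onnela_clustering(Ws, n);
    Ls[s] = char_path_length(Ws, n);
  }
  return List::create(_["C"] = Cs, _["L"] = Ls);
}
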