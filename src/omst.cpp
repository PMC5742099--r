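#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression + union by rank.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Repeated Kruskal rounds over residual graphs: round r runs Kruskal on the
// edges not selected in rounds 1..r-1. `ei`, `ej` are 1-based endpoints
// already sorted by (distance, i, j). Returns the 1-based round index per
// edge (0 = never selected within max_rounds).
// [[Rcpp::export]]
IntegerVector omst_rounds_cpp(int n, IntegerVector ei, IntegerVector ej,
                              int max_rounds) {
  int m = ei.size();
  IntegerVector round_of(m);
  std::fill(round_of.begin(), round_of.end(), 0);
  int remaining = m;
  for (int r = 1; r <= max_rounds && remaining > 0; ++r) {
    std::vector<int> parent(n), rank_(n, 0);
    for (int v = 0; v < n; ++v) parent[v] = v;
    int accepted = 0;
    for (int e = 0; e < m; ++e) {
      if (round_of[e] != 0) continue;
      int a = uf_find(parent, ei[e] - 1);
      int b = uf_find(parent, ej[e] - 1);
      if (a == b) continue;
      if (rank_[a] < rank_[b]) std::swap(a, b);
      parent[b] = a;
      if (rank_[a] == rank_[b]) rank_[a]++;
      round_of[e] = r;
      ++accepted;
      if (accepted == n - 1) break;
    }
    if (accepted == 0) break;
    remaining -= accepted;
  }
  return round_of;
}
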