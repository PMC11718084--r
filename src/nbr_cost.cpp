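// Exact one-hop neighborhood alignment costs for the bipartite-matching
// bound, for all type-compatible node pairs at once. The per-pair problem
// is a tiny assignment: incident edges of u versus incident edges of v,
// pairable only when the opposite endpoints share an atom type (cost
// |b1 - b2|), with unpaired edges costing their full weight. Degrees are
// bounded by the valence cap, so a subset-DP over the columns is exact
// and cheap. All weights are integer quarter-units.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".nbr_costs_cpp")]]
IntegerMatrix nbr_costs_cpp(IntegerVector a1, IntegerVector a2,
                            IntegerMatrix W1, IntegerMatrix W2) {
  const int n1 = a1.size(), n2 = a2.size();
  const int BIG = NA_INTEGER;

  // incident lists: (weight, opposite atom type)
  std::vector<std::vector<std::pair<int, int>>> inc1(n1), inc2(n2);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n1; ++j)
      if (W1(i, j) > 0) inc1[i].push_back({W1(i, j), a1[j]});
  for (int k = 0; k < n2; ++k)
    for (int l = 0; l < n2; ++l)
      if (W2(k, l) > 0) inc2[k].push_back({W2(k, l), a2[l]});

  IntegerMatrix out(n1, n2);
  std::vector<int> dp, ndp;
  for (int i = 0; i < n1; ++i) {
    for (int k = 0; k < n2; ++k) {
      if (a1[i] != a2[k]) { out(i, k) = BIG; continue; }
      const auto& eu = inc1[i];
      const auto& ev = inc2[k];
      const int r = (int)eu.size(), c = (int)ev.size();
      const int nmask = 1 << c;
      // dp[mask] = min cost of the processed rows using column set mask
      dp.assign(nmask, INT_MAX / 2);
      dp[0] = 0;
      for (int row = 0; row < r; ++row) {
        ndp.assign(nmask, INT_MAX / 2);
        for (int mask = 0; mask < nmask; ++mask) {
          if (dp[mask] >= INT_MAX / 2) continue;
          int skip = dp[mask] + eu[row].first;  // row edge left unpaired
          if (skip < ndp[mask]) ndp[mask] = skip;
          for (int col = 0; col < c; ++col) {
            if (mask & (1 << col)) continue;
            int cost = (eu[row].second == ev[col].second)
                           ? std::abs(eu[row].first - ev[col].first)
                           : eu[row].first + ev[col].first;
            int v = dp[mask] + cost;
            if (v < ndp[mask | (1 << col)]) ndp[mask | (1 << col)] = v;
          }
        }
        dp.swap(ndp);
      }
      int best = INT_MAX;
      for (int mask = 0; mask < nmask; ++mask) {
        if (dp[mask] >= INT_MAX / 2) continue;
        int leftover = 0;
        for (int col = 0; col < c; ++col)
          if (!(mask & (1 << col))) leftover += ev[col].first;
        best = std::min(best, dp[mask] + leftover);
      }
      out(i, k) = best;
    }
  }
  return out;
}
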