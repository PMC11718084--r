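// Exact weighted Maximum Common Edge Subgraph distance by depth-first
// branch-and-bound over injective, type-consistent node mappings.
//
// Semantics match the integer-program formulation used elsewhere in the
// package: minimize sum |b1 - b2| over common edges plus the weight of all
// uncommon edges. A distance threshold T enters as a search cutoff, which
// is exactly the role of the ILP's threshold constraint: if no mapping of
// cost <= T exists the instance is reported infeasible. All weights are
// integer quarter-units.
//
// The accumulated cost of a partial mapping is a valid lower bound on any
// completion (future decisions only add non-negative terms and the
// untouched weight of G2, tracked in rem2, is added at the leaf), so
// pruning on cost >= min(incumbent, cutoff + 1) preserves optimality.

#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <vector>

using namespace Rcpp;

namespace {

struct Search {
  int n1 = 0, n2 = 0;
  std::vector<int> a1, a2;        // atom-type codes
  std::vector<int> W1, W2;        // dense adjacency, quarter units
  std::vector<int> order;         // V1 nodes in processing order
  std::vector<std::vector<int>> cand;  // candidates in G2 per position
  std::vector<int> assign;        // per position: node of G2 (-1 unmapped)
  std::vector<char> used;
  long long best = 0, cutoff = 0;
  std::vector<int> best_assign;
  bool found = false, timed_out = false;
  double time_limit = -1.0;
  std::chrono::steady_clock::time_point t0;
  long long ticks = 0;

  int w1(int i, int j) const { return W1[i * n1 + j]; }
  int w2(int k, int l) const { return W2[k * n2 + l]; }

  // dead1[i]: weight from node i into already-unmapped processed nodes —
  // charged no matter how i is decided, so summing it over unprocessed
  // nodes (future_dead) is an admissible addition to the cost bound
  std::vector<long long> dead1;
  std::vector<char> processed;
  long long future_dead = 0;

  bool out_of_time() {
    if (time_limit <= 0) return false;
    if ((++ticks & 0x1FFF) != 0) return timed_out;
    double el = std::chrono::duration<double>(
                    std::chrono::steady_clock::now() - t0).count();
    if (el > time_limit) timed_out = true;
    return timed_out;
  }

  void dfs(int pos, long long cost, long long rem2) {
    if (timed_out || out_of_time()) return;
    long long lim = found ? std::min(best - 1, cutoff) : cutoff;
    if (cost + future_dead > lim) return;
    if (pos == n1) {
      long long total = cost + rem2;
      if (total <= cutoff && (!found || total < best)) {
        best = total;
        best_assign = assign;
        found = true;
      }
      return;
    }
    int i = order[pos];
    processed[i] = 1;
    future_dead -= dead1[i];
    for (int k : cand[pos]) {
      if (used[k]) continue;
      long long add = 0, covered = 0;
      for (int p = 0; p < pos; ++p) {
        int j = order[p], l = assign[p];
        int e1 = w1(i, j);
        if (l < 0) {
          add += e1;
        } else {
          int e2 = w2(k, l);
          if (e1 > 0 && e2 > 0) {
            add += std::abs(e1 - e2);
            covered += e2;
          } else if (e1 > 0) {
            add += e1;
          } else if (e2 > 0) {
            add += e2;
            covered += e2;
          }
        }
      }
      assign[pos] = k;
      used[k] = 1;
      dfs(pos + 1, cost + add, rem2 - covered);
      used[k] = 0;
      assign[pos] = -1;
    }
    // leave i unmapped: edges to already-processed nodes become uncommon
    // now; edges to unprocessed nodes become guaranteed future cost
    long long add = 0;
    for (int p = 0; p < pos; ++p) add += w1(i, order[p]);
    for (int j = 0; j < n1; ++j) {
      if (processed[j]) continue;
      dead1[j] += w1(i, j);
      future_dead += w1(i, j);
    }
    assign[pos] = -1;
    dfs(pos + 1, cost + add, rem2);
    for (int j = 0; j < n1; ++j) {
      if (processed[j]) continue;
      dead1[j] -= w1(i, j);
      future_dead -= w1(i, j);
    }
    processed[i] = 0;
    future_dead += dead1[i];
  }
};

}  // namespace

// [[Rcpp::export(name = ".mces_bb_cpp")]]
List mces_bb_cpp(IntegerVector a1, IntegerVector a2, IntegerMatrix W1,
                 IntegerMatrix W2, double cutoff4, double time_limit) {
  Search s;
  s.n1 = a1.size();
  s.n2 = a2.size();
  s.a1.assign(a1.begin(), a1.end());
  s.a2.assign(a2.begin(), a2.end());
  s.W1.assign(W1.begin(), W1.end());  // symmetric, so layout is irrelevant
  s.W2.assign(W2.begin(), W2.end());
  s.time_limit = time_limit;
  s.t0 = std::chrono::steady_clock::now();

  long long tot1 = 0, tot2 = 0;
  std::vector<long long> wd1(s.n1, 0), wd2(s.n2, 0);
  for (int i = 0; i < s.n1; ++i)
    for (int j = 0; j < s.n1; ++j) wd1[i] += s.w1(i, j);
  for (int k = 0; k < s.n2; ++k)
    for (int l = 0; l < s.n2; ++l) wd2[k] += s.w2(k, l);
  for (int i = 0; i < s.n1; ++i) tot1 += wd1[i];
  for (int k = 0; k < s.n2; ++k) tot2 += wd2[k];
  tot1 /= 2;
  tot2 /= 2;

  s.cutoff = cutoff4 < 0 ? tot1 + tot2 : (long long)cutoff4;

  // process V1 by descending weighted degree; heavy nodes constrain most
  s.order.resize(s.n1);
  for (int i = 0; i < s.n1; ++i) s.order[i] = i;
  std::stable_sort(s.order.begin(), s.order.end(),
                   [&](int a, int b) { return wd1[a] > wd1[b]; });

  s.cand.resize(s.n1);
  for (int pos = 0; pos < s.n1; ++pos) {
    int i = s.order[pos];
    std::vector<int>& c = s.cand[pos];
    for (int k = 0; k < s.n2; ++k)
      if (s.a2[k] == s.a1[i]) c.push_back(k);
    std::stable_sort(c.begin(), c.end(), [&](int x, int y) {
      return std::llabs(wd2[x] - wd1[i]) < std::llabs(wd2[y] - wd1[i]);
    });
  }

  s.assign.assign(s.n1, -1);
  s.used.assign(s.n2, 0);
  s.dead1.assign(s.n1, 0);
  s.processed.assign(s.n1, 0);

  // the all-unmapped solution is always feasible when within the cutoff
  if (tot1 + tot2 <= s.cutoff) {
    s.best = tot1 + tot2;
    s.best_assign = s.assign;
    s.found = true;
  }
  s.dfs(0, 0, tot2);

  IntegerVector map(s.n1, NA_INTEGER);
  if (s.found)
    for (int pos = 0; pos < s.n1; ++pos)
      if (s.best_assign[pos] >= 0) map[s.order[pos]] = s.best_assign[pos] + 1;

  int status = s.timed_out ? 2 : (s.found ? 0 : 1);
  return List::create(_["status"] = status,
                      _["obj4"] = s.found ? (double)s.best : NA_REAL,
                      _["map"] = map);
}
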