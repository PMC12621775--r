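#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Co-linear chaining DP over anchors (pass 1) or fragments (pass 2).
//
// Items must be sorted by read start (ties by graph address). For each item
// j, predecessors i are scanned backwards under a lookback cap. A link is
// admissible when the read and graph coordinates both advance strictly, the
// read/graph gaps respect the pass limits, and the graph route is usable:
// two items whose snarl-tree ancestries first diverge at different children
// of a non-tangled snarl are on parallel alleles and cannot be linked.
// Link cost is the Minimap2-style gap cost on g = |read_gap - graph_gap|:
// 0 if g == 0, else c_lin * k * g + c_log * log2(g). The DP maximizes
// sum(newly covered read bases) * match_bonus - sum(gap costs).
//
// anc_s / anc_e: per-item snarl-tree ancestry at the item's start/end node,
// rows of (structure id, rank) pairs flattened to 2*L columns, padded -1.
// kind / tangled are indexed by structure id (1-based): kind 1 = chain,
// 2 = snarl; tangled marks snarls whose children are mutually reachable.
// [[Rcpp::export]]
List chain_dp_cpp(const IntegerVector &rs, const IntegerVector &re,
                  const NumericVector &ga_s, const NumericVector &ga_e,
                  const IntegerMatrix &anc_s, const IntegerMatrix &anc_e,
                  const IntegerVector &kind, const LogicalVector &tangled,
                  const NumericVector &item_score,
                  double match_bonus, double c_lin, double c_log, int k,
                  double max_read_gap, double max_graph_gap, int lookback) {
  const int n = rs.size();
  const int L = anc_s.ncol() / 2;
  NumericVector dp(n);
  IntegerVector prev(n);
  for (int j = 0; j < n; ++j) {
    dp[j] = item_score[j];
    prev[j] = 0;
    int considered = 0;
    for (int i = j - 1; i >= 0; --i) {
      if (rs[j] - rs[i] > max_read_gap + 1000) break;
      if (++considered > lookback) break;
      if (rs[i] >= rs[j] || re[i] >= re[j]) continue;
      double dg = ga_s[j] - ga_s[i];
      if (!(dg > 0)) continue;
      if (ga_e[j] <= ga_e[i]) continue;
      double dr = (double)(rs[j] - rs[i]);
      double read_gap = (double)(rs[j] - re[i] - 1);
      double graph_gap = ga_s[j] - ga_e[i] - 1.0;
      if (read_gap > max_read_gap || graph_gap > max_graph_gap) continue;
      // ancestry compatibility
      bool ok = true;
      for (int l = 0; l < L; ++l) {
        int sid_i = anc_e(i, 2 * l), sid_j = anc_s(j, 2 * l);
        if (sid_i < 0 || sid_j < 0) break;  // ran out: same path so far
        if (sid_i != sid_j) { ok = false; break; }  // different components
        int rk_i = anc_e(i, 2 * l + 1), rk_j = anc_s(j, 2 * l + 1);
        if (rk_i != rk_j) {
          if (kind[sid_i - 1] == 2 && !tangled[sid_i - 1]) ok = false;
          break;  // first divergence decides
        }
      }
      if (!ok) continue;
      double g = std::fabs(dr - dg);
      double cost = (g == 0) ? 0.0 : (c_lin * k * g + c_log * std::log2(g));
      double overlap = std::max(0.0, (double)(re[i] - rs[j] + 1));
      double cand = dp[i] + item_score[j] - match_bonus * overlap - cost;
      if (cand > dp[j]) { dp[j] = cand; prev[j] = i + 1; }
    }
  }
  return List::create(_["dp"] = dp, _["prev"] = prev);
}
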