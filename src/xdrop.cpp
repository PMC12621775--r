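#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// X-drop extension alignment of a query tail against a single target string.
// Both sequences start at the anchor end; the alignment may stop anywhere
// (best-scoring cell wins; the remaining query is a soft clip). Gap-affine
// scoring with an adaptive band of half-width `band` recentred each row on
// the best cell of the previous row (Dozeu-style), and X-drop termination:
// extension stops once a whole row scores more than x_drop below the best
// cell seen. Returns best score, query/target bases consumed, and CIGAR.
// [[Rcpp::export]]
List xdrop_extend_cpp(const std::string &query, const std::string &target,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int x_drop, int band) {
  const int n = (int)query.size(), m = (int)target.size();
  const int NEG = INT_MIN / 4;
  struct Row {
    int lo, hi;
    std::vector<int> M, I, D;
    std::vector<uint8_t> bM, bI, bD;
  };
  std::vector<Row> rows;
  rows.reserve(n + 1);
  // row 0: leading deletions (target consumed, no query)
  {
    Row r; r.lo = 0;
    int hi = 0;
    while (hi < m) {
      int sc = -gap_open - (hi + 1) * gap_extend;
      if (sc <= -x_drop || hi + 1 > 2 * band) break;
      ++hi;
    }
    r.hi = hi;
    int wdt = hi + 1;
    r.M.assign(wdt, NEG); r.I.assign(wdt, NEG); r.D.assign(wdt, NEG);
    r.bM.assign(wdt, 0); r.bI.assign(wdt, 0); r.bD.assign(wdt, 0);
    r.M[0] = 0; r.D[0] = NEG;
    for (int h = 1; h <= hi; ++h) {
      r.D[h] = -gap_open - h * gap_extend;
      r.M[h] = r.D[h];
      r.bD[h] = 4 | (h > 1 ? 8 : 0);
      r.bM[h] = 4 | (h > 1 ? 8 : 0);
    }
    rows.push_back(std::move(r));
  }
  int best = 0, best_v = 0, best_h = 0, prev_center = 0;
  for (int v = 1; v <= n; ++v) {
    const Row &p = rows[v - 1];
    int lo = std::max(0, prev_center + 1 - band);
    int hi = std::min(m, prev_center + 1 + band);
    if (lo > hi) break;
    Row r; r.lo = lo; r.hi = hi;
    int wdt = hi - lo + 1;
    r.M.assign(wdt, NEG); r.I.assign(wdt, NEG); r.D.assign(wdt, NEG);
    r.bM.assign(wdt, 0); r.bI.assign(wdt, 0); r.bD.assign(wdt, 0);
    int row_best = NEG, row_arg = lo;
    bool qvalid = query[v - 1] == 'A' || query[v - 1] == 'C' ||
                  query[v - 1] == 'G' || query[v - 1] == 'T';
    for (int h = lo; h <= hi; ++h) {
      int j = h - lo;
      // I: from row above, same column
      int pM = (h >= p.lo && h <= p.hi) ? p.M[h - p.lo] : NEG;
      int pI = (h >= p.lo && h <= p.hi) ? p.I[h - p.lo] : NEG;
      int i_open = (pM > NEG) ? pM - gap_open - gap_extend : NEG;
      int i_ext = (pI > NEG) ? pI - gap_extend : NEG;
      r.I[j] = std::max(i_open, i_ext);
      r.bI[j] = (i_ext > i_open) ? (3 | 8) : 3;
      // D: from left in this row
      int lM = (j > 0) ? r.M[j - 1] : NEG;
      int lD = (j > 0) ? r.D[j - 1] : NEG;
      int d_open = (lM > NEG) ? lM - gap_open - gap_extend : NEG;
      int d_ext = (lD > NEG) ? lD - gap_extend : NEG;
      r.D[j] = std::max(d_open, d_ext);
      r.bD[j] = (d_ext > d_open) ? (4 | 8) : 4;
      // M: diagonal from row above, column h-1
      int dM = (h - 1 >= p.lo && h - 1 <= p.hi) ? p.M[h - 1 - p.lo] : NEG;
      bool is_match = qvalid && h >= 1 && query[v - 1] == target[h - 1];
      int diag = (h >= 1 && dM > NEG) ? dM + (is_match ? match : -mismatch) : NEG;
      int mv = std::max(std::max(diag, r.I[j]), r.D[j]);
      if (mv <= NEG) { r.M[j] = NEG; continue; }
      r.M[j] = mv;
      if (mv == diag) r.bM[j] = is_match ? 1 : 2;
      else if (mv == r.I[j]) r.bM[j] = r.bI[j];
      else r.bM[j] = r.bD[j];
      if (mv < best - x_drop) { r.M[j] = NEG; continue; }
      if (mv > row_best) { row_best = mv; row_arg = h; }
      if (mv > best) { best = mv; best_v = v; best_h = h; }
    }
    rows.push_back(std::move(r));
    if (row_best <= best - x_drop || row_best <= NEG) break;
    prev_center = row_arg;
  }
  // traceback from the best cell through M
  std::string ops;
  int v = best_v, h = best_h; char comp = 'M';
  while (v > 0 || h > 0) {
    const Row &r = rows[v];
    if (h < r.lo || h > r.hi) break;  // safety
    uint8_t b = (comp == 'M') ? r.bM[h - r.lo] :
                (comp == 'I') ? r.bI[h - r.lo] : r.bD[h - r.lo];
    uint8_t dir = b & 7;
    if (comp == 'M') {
      if (dir == 1) { ops.push_back('='); --v; --h; }
      else if (dir == 2) { ops.push_back('X'); --v; --h; }
      else if (dir == 3) comp = 'I';
      else if (dir == 4) comp = 'D';
      else break;
    } else if (comp == 'I') {
      ops.push_back('I'); --v;
      comp = (b & 8) ? 'I' : 'M';
    } else {
      ops.push_back('D'); --h;
      comp = (b & 8) ? 'D' : 'M';
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::vector<std::string> op_out; std::vector<int> len_out;
  for (char c : ops) {
    if (!op_out.empty() && op_out.back()[0] == c) ++len_out.back();
    else { op_out.push_back(std::string(1, c)); len_out.push_back(1); }
  }
  return List::create(_["score"] = best, _["query_used"] = best_v,
                      _["target_used"] = best_h,
                      _["ops"] = wrap(op_out), _["lens"] = wrap(len_out));
}
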