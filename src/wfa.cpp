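#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Gap-affine wavefront alignment (WFA) for global alignment of two strings.
//
// Works in the cost-minimizing formulation (match cost 0). A score-maximizing
// problem with match bonus a, mismatch penalty b, gap open o, gap extend e is
// converted to integer costs x = 2(a+b), o' = 2o, e' = 2e + a; the optimal
// score is recovered as (a*(n+m) - cost)/2. Wavefronts are stored per cost so
// the traceback can reconstruct the CIGAR.
//
// Diagonals: k = h - v, where h indexes the target (text) and v the query
// (pattern). Offsets store h. M/I/D components; I = gap in target
// consuming query (insertion to target's view -> 'I' op = extra query base),
// D = deletion (extra target base).

static const int NEG = INT_MIN / 4;

struct WF {
  int lo, hi;                 // diagonal range
  std::vector<int> m, i, d;   // offsets per diagonal (h), NEG if unset
  int at(const std::vector<int> &vv, int k) const {
    if (k < lo || k > hi) return NEG;
    return vv[k - lo];
  }
};

// [[Rcpp::export]]
List wfa_align_cpp(const std::string &query, const std::string &target,
                   int match, int mismatch, int gap_open, int gap_extend,
                   double max_cost) {
  const int n = (int)query.size();   // pattern (v)
  const int m = (int)target.size();  // text (h)
  const int x = 2 * (match + mismatch);
  const int o = 2 * gap_open;
  const int e = 2 * gap_extend + match;
  const int kfin = m - n;
  // max admissible cost in doubled units
  long long cap = (max_cost >= 0 && R_finite(max_cost))
    ? (long long)(2.0 * max_cost) : LLONG_MAX / 4;

  std::vector<WF> wfs;  // wavefront per cost s
  auto extend = [&](int k, int h) {
    int v = h - k;
    while (h < m && v < n && target[h] == query[v]) { ++h; ++v; }
    return h;
  };

  // s = 0
  {
    WF w; w.lo = 0; w.hi = 0;
    w.m = {extend(0, 0)}; w.i = {NEG}; w.d = {NEG};
    wfs.push_back(w);
    if (n == 0 && m == 0) {
      return List::create(_["ok"] = true, _["cost"] = 0.0,
                          _["score"] = 0.0, _["ops"] = CharacterVector(0),
                          _["lens"] = IntegerVector(0));
    }
    if (w.m[0] >= m && w.m[0] - 0 >= n && w.m[0] == m && m - kfin == n) {
      // immediate full match
      if (w.m[0] == m && kfin == 0) {
        return List::create(_["ok"] = true, _["cost"] = 0.0,
                            _["score"] = (double)(match * n),
                            _["ops"] = CharacterVector::create("="),
                            _["lens"] = IntegerVector::create(n));
      }
    }
  }

  int s_final = -1;
  for (int s = 1; (long long)s <= cap; ++s) {
    // compute new wavefront from s-x, s-o-e, s-e
    const WF *wx = (s - x >= 0) ? &wfs[s - x] : nullptr;
    const WF *wo = (s - o - e >= 0) ? &wfs[s - o - e] : nullptr;
    const WF *we = (s - e >= 0) ? &wfs[s - e] : nullptr;
    int lo = INT_MAX, hi = INT_MIN;
    if (wx) { lo = std::min(lo, wx->lo - 0); hi = std::max(hi, wx->hi); }
    if (wo) { lo = std::min(lo, wo->lo - 1); hi = std::max(hi, wo->hi + 1); }
    if (we) { lo = std::min(lo, we->lo - 1); hi = std::max(hi, we->hi + 1); }
    WF w;
    if (lo == INT_MAX) { w.lo = 0; w.hi = -1; wfs.push_back(w); continue; }
    // keep diagonals within the feasible band
    lo = std::max(lo, -n); hi = std::min(hi, m);
    w.lo = lo; w.hi = hi;
    int width = hi - lo + 1;
    if (width < 0) { w.lo = 0; w.hi = -1; wfs.push_back(w); continue; }
    w.m.assign(width, NEG); w.i.assign(width, NEG); w.d.assign(width, NEG);
    bool done = false;
    for (int k = lo; k <= hi; ++k) {
      // I: gap consuming query (v advances, h stays): from diagonal k+1
      int ii = NEG;
      if (wo) ii = std::max(ii, wo->at(wo->m, k + 1));
      if (we) ii = std::max(ii, we->at(we->i, k + 1));
      // D: gap consuming target (h advances): from diagonal k-1, offset+1
      int dd = NEG;
      if (wo) { int t = wo->at(wo->m, k - 1); if (t > NEG) dd = std::max(dd, t + 1); }
      if (we) { int t = we->at(we->d, k - 1); if (t > NEG) dd = std::max(dd, t + 1); }
      // M: mismatch from same diagonal, offset+1; or close a gap
      int mm = NEG;
      if (wx) { int t = wx->at(wx->m, k); if (t > NEG) mm = std::max(mm, t + 1); }
      mm = std::max(mm, ii);
      mm = std::max(mm, dd);
      // clip to valid cell range on this diagonal
      if (ii > NEG && (ii > m || ii - k > n)) ii = NEG;
      if (dd > NEG && (dd > m || dd - k > n)) dd = NEG;
      if (mm > NEG && (mm > m || mm - k > n)) mm = NEG;
      if (mm > NEG) mm = extend(k, mm);
      w.i[k - lo] = ii; w.d[k - lo] = dd; w.m[k - lo] = mm;
      if (k == kfin && mm >= m) done = true;
    }
    wfs.push_back(w);
    if (done) { s_final = s; break; }
  }
  if (s_final < 0) {
    return List::create(_["ok"] = false, _["cost"] = NA_REAL,
                        _["score"] = NA_REAL, _["ops"] = CharacterVector(0),
                        _["lens"] = IntegerVector(0));
  }

  // Traceback from (s_final, kfin, component M, offset m).
  std::string ops;  // built reversed
  int s = s_final, k = kfin, h = m;
  char comp = 'M';
  while (true) {
    if (comp == 'M') {
      // undo the match extension down to the entry point of this M cell
      int entry;
      // recompute what mm was before extension
      const WF *wx = (s - x >= 0) ? &wfs[s - x] : nullptr;
      const WF *wo = (s - o - e >= 0) ? &wfs[s - o - e] : nullptr;
      const WF *we = (s - e >= 0) ? &wfs[s - e] : nullptr;
      int ii = NEG, dd = NEG, mm = NEG;
      if (s > 0) {
        if (wo) ii = std::max(ii, wo->at(wo->m, k + 1));
        if (we) ii = std::max(ii, we->at(we->i, k + 1));
        if (wo) { int t = wo->at(wo->m, k - 1); if (t > NEG) dd = std::max(dd, t + 1); }
        if (we) { int t = we->at(we->d, k - 1); if (t > NEG) dd = std::max(dd, t + 1); }
        if (wx) { int t = wx->at(wx->m, k); if (t > NEG) mm = t + 1; }
      }
      int best = std::max(std::max(ii, dd), mm);
      if (s == 0 || best == NEG) entry = 0; else entry = best;
      int nmatch = h - entry;
      for (int t = 0; t < nmatch; ++t) ops.push_back('=');
      h = entry;
      if (s == 0) break;
      if (mm >= ii && mm >= dd) { comp = 'M'; s -= x; h -= 1; ops.push_back('X'); }
      else if (ii >= dd) { comp = 'I'; }
      else { comp = 'D'; }
      if (comp == 'M') {
        if (s == 0 && h == 0 && k == 0) { /* will close next loop */ }
      }
    } else if (comp == 'I') {
      // came from diagonal k+1 (query base consumed)
      const WF *wo = (s - o - e >= 0) ? &wfs[s - o - e] : nullptr;
      const WF *we = (s - e >= 0) ? &wfs[s - e] : nullptr;
      int open_src = wo ? wo->at(wo->m, k + 1) : NEG;
      int ext_src = we ? we->at(we->i, k + 1) : NEG;
      ops.push_back('I');
      if (ext_src > NEG && ext_src >= open_src) { comp = 'I'; s -= e; k += 1; }
      else { comp = 'M'; s -= o + e; k += 1; }
    } else {  // 'D'
      const WF *wo = (s - o - e >= 0) ? &wfs[s - o - e] : nullptr;
      const WF *we = (s - e >= 0) ? &wfs[s - e] : nullptr;
      int open_src = wo ? wo->at(wo->m, k - 1) : NEG;
      int ext_src = we ? we->at(we->d, k - 1) : NEG;
      ops.push_back('D');
      h -= 1;
      if (ext_src > NEG && ext_src >= open_src) { comp = 'D'; s -= e; k -= 1; }
      else { comp = 'M'; s -= o + e; k -= 1; }
    }
    if (comp == 'M' && s == 0) {
      // finish remaining matches on diagonal 0
      // (loop continues; M branch with s==0 emits them and breaks)
      if (k != 0) {
        // shouldn't happen; guard against infinite loop
        break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::vector<std::string> op_out;
  std::vector<int> len_out;
  for (size_t i2 = 0; i2 < ops.size(); ++i2) {
    if (!op_out.empty() && op_out.back()[0] == ops[i2]) ++len_out.back();
    else { op_out.push_back(std::string(1, ops[i2])); len_out.push_back(1); }
  }
  double cost = s_final / 2.0;
  double score = (match * (double)(n + m) - s_final) / 2.0;
  return List::create(_["ok"] = true, _["cost"] = cost, _["score"] = score,
                      _["ops"] = wrap(op_out), _["lens"] = wrap(len_out));
}
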