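#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Reverse complement of a single DNA string (A/C/G/T/N, case-insensitive).
// [[Rcpp::export]]
std::string rc_string_cpp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// splitmix64 finalizer: invertible 64-bit mix, fixed constants for
// reproducibility across platforms.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// (w,k)-minimizers of one sequence. Returns 1-based start positions of the
// selected k-mers, their canonical-strand hash (truncated to 52 bits so it is
// exactly representable as an R double), and the strand of the canonical
// k-mer (+1 if the forward spelling is canonical, -1 otherwise).
// K-mers containing non-ACGT characters are skipped.
// [[Rcpp::export]]
List minimizers_cpp(const std::string &seq, const int k, const int w) {
  const int64_t n = (int64_t)seq.size();
  std::vector<int> pos_out;
  std::vector<double> hash_out;
  std::vector<int> strand_out;
  if (n < k || k < 1 || k > 31 || w < 1) {
    return List::create(_["pos"] = IntegerVector(0),
                        _["hash"] = NumericVector(0),
                        _["strand"] = IntegerVector(0));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const uint64_t hmask = (1ULL << 52) - 1;
  const int64_t nk = n - k + 1;  // number of k-mer starts
  std::vector<double> hash(nk, -1.0);
  std::vector<int8_t> strand(nk, 0);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // run of valid bases ending at current position
  for (int64_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++valid;
    if (valid >= k) {
      int64_t start = i - k + 1;
      uint64_t hf = mix64(fwd), hr = mix64(rev);
      if (hf <= hr) { hash[start] = (double)(hf & hmask); strand[start] = 1; }
      else          { hash[start] = (double)(hr & hmask); strand[start] = -1; }
    }
  }
  // sliding-window minimum over hash[], window of w k-mer starts
  std::deque<int64_t> dq;
  int64_t last_emitted = -1;
  for (int64_t i = 0; i < nk; ++i) {
    if (hash[i] >= 0) {
      while (!dq.empty() && hash[dq.back()] >= hash[i]) dq.pop_back();
      dq.push_back(i);
    }
    while (!dq.empty() && dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1 && !dq.empty()) {
      int64_t m = dq.front();
      if (m != last_emitted) {
        pos_out.push_back((int)(m + 1));
        hash_out.push_back(hash[m]);
        strand_out.push_back(strand[m]);
        last_emitted = m;
      }
    }
  }
  return List::create(_["pos"] = wrap(pos_out),
                      _["hash"] = wrap(hash_out),
                      _["strand"] = wrap(strand_out));
}
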