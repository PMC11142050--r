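#ifndef MHCFORGE_CORE_H
#define MHCFORGE_CORE_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': return 'N'; case 'n': return 'n';
  default:  return 'N';
  }
}

inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

inline std::string canonical_kmer(const std::string &s) {
  std::string r = revcomp(s);
  return (r < s) ? r : s;
}

inline bool has_n(const std::string &s, size_t from, size_t len) {
  for (size_t i = from; i < from + len; ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return true;
  }
  return false;
}

// ---- 2-bit packed k-mers ----
// A=0 C=1 G=2 T=3; complement b -> 3-b. k <= 63 fits an unsigned __int128.

typedef unsigned __int128 kmer_t;

inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline kmer_t kmer_mask(int k) {
  return (((kmer_t)1) << (2 * k)) - 1;
}

inline kmer_t kmer_rc(kmer_t x, int k) {
  kmer_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (int)(x & 3));
    x >>= 2;
  }
  return r;
}

inline std::string kmer_decode(kmer_t x, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[(int)(x & 3)]; x >>= 2; }
  return s;
}

struct KmerHash {
  size_t operator()(const kmer_t &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x517CC1B727220A95ULL);
    h ^= h >> 29; h *= 0xBF58476D1CE4E5B9ULL; h ^= h >> 32;
    return (size_t)h;
  }
};

// rolling scan over a sequence: calls f(pos, fwd, rev) for every valid
// (N-free) k-mer window; pos is the 0-based start
template <typename F>
inline void kmer_scan(const std::string &s, int k, F f) {
  const long n = (long)s.size();
  if (n < k) return;
  kmer_t fwd = 0, rev = 0, mask = kmer_mask(k);
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (long i = 0; i < n; ++i) {
    int b = base2(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (kmer_t)b) & mask;
    rev = (rev >> 2) | ((kmer_t)(3 - b) << shift);
    if (++valid >= k) f(i - k + 1, fwd, rev);
  }
}

// affine-gap scoring; gap of length g costs gap_open + gap_ext * g
struct Scoring {
  double match, mismatch, gap_open, gap_ext;
};

struct AlnResult {
  double score;
  int tstart, tend;     // 0-based half-open on target
  std::string cigar;    // ops M (match), X (mismatch), I (query ins), D (query del)
  int matches;
  bool ok;
};

// query aligned end-to-end, target ends free (glocal)
AlnResult align_glocal(const std::string &q, const std::string &t, const Scoring &sc);
// both sequences aligned end-to-end
AlnResult align_global(const std::string &a, const std::string &b, const Scoring &sc);

#endif
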