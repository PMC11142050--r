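#include "core.h"
#include <map>
#include <tuple>
using namespace Rcpp;

// k-mer census over a read set: how many distinct canonical k-mers occur
// exactly once, plus totals. Used for the unique-150mer read statistic.
// [[Rcpp::export]]
List cpp_kmer_census(CharacterVector reads, int k, bool canonical = true) {
  std::unordered_map<std::string, int> tab;
  long n_used = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    ++n_used;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      if (has_n(s, i, k)) continue;
      std::string km = s.substr(i, k);
      if (canonical) km = canonical_kmer(km);
      tab[km]++;
    }
  }
  double once = 0;
  for (auto &kv : tab) if (kv.second == 1) once += 1;
  return List::create(_["n_reads_used"] = (double)n_used,
                      _["n_distinct"] = (double)tab.size(),
                      _["n_singleton"] = once);
}

// count reads containing at least one k-mer unique to a single exemplar group
// groups: group label per exemplar sequence
// [[Rcpp::export]]
IntegerVector cpp_group_kmer_hits(CharacterVector reads, CharacterVector exemplars,
                                  CharacterVector groups, int k) {
  std::vector<std::string> glab;
  std::unordered_map<std::string, int> gid;
  for (R_xlen_t i = 0; i < groups.size(); ++i) {
    std::string g = as<std::string>(groups[i]);
    if (!gid.count(g)) { gid[g] = (int)glab.size(); glab.push_back(g); }
  }
  if (k > 63) stop("k must be <= 63");
  // canonical kmer -> group id, or -1 if shared between groups
  std::unordered_map<kmer_t, int, KmerHash> owner;
  for (R_xlen_t i = 0; i < exemplars.size(); ++i) {
    std::string s = as<std::string>(exemplars[i]);
    int g = gid[as<std::string>(groups[i])];
    kmer_scan(s, k, [&](long, kmer_t fwd, kmer_t rev) {
      kmer_t c = fwd < rev ? fwd : rev;
      auto it = owner.find(c);
      if (it == owner.end()) owner[c] = g;
      else if (it->second != g) it->second = -1;
    });
  }
  IntegerVector counts(glab.size());
  counts.attr("names") = wrap(glab);
  std::vector<char> hit(glab.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    std::fill(hit.begin(), hit.end(), 0);
    kmer_scan(s, k, [&](long, kmer_t fwd, kmer_t rev) {
      kmer_t c = fwd < rev ? fwd : rev;
      auto it = owner.find(c);
      if (it != owner.end() && it->second >= 0) hit[it->second] = 1;
    });
    for (size_t g = 0; g < hit.size(); ++g) if (hit[g]) counts[g]++;
  }
  return counts;
}

// quality trimming: leading/trailing bases with Q < lead_trail_q or base N are
// stripped, then 5'->3' sliding windows of `window` bases truncate the read at
// the first window whose mean quality is <= window_q. Returns 1-based
// keep-range [start, end]; end < start means the whole read is discarded.
// [[Rcpp::export]]
List cpp_trim_batch(CharacterVector seqs, CharacterVector quals,
                    int lead_trail_q, int window, double window_q,
                    int qual_offset = 33) {
  R_xlen_t n = seqs.size();
  IntegerVector start(n), end(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    if (s.size() != q.size()) stop("sequence/quality length mismatch in record %d", (int)(r + 1));
    int L = (int)s.size();
    int lo = 0, hi = L; // half-open keep range
    while (lo < hi) {
      int qv = (int)q[lo] - qual_offset;
      char b = s[lo];
      if (qv < lead_trail_q || b == 'N' || b == 'n') ++lo; else break;
    }
    while (hi > lo) {
      int qv = (int)q[hi - 1] - qual_offset;
      char b = s[hi - 1];
      if (qv < lead_trail_q || b == 'N' || b == 'n') --hi; else break;
    }
    // sliding window truncation
    for (int i = lo; i + window <= hi; ++i) {
      double sum = 0;
      for (int w = 0; w < window; ++w) sum += (int)q[i + w] - qual_offset;
      if (sum / window <= window_q) { hi = i; break; }
    }
    start[r] = lo + 1;
    end[r] = hi;
  }
  return List::create(_["start"] = start, _["end"] = end);
}

// suffix-prefix / containment overlap candidates between contigs, by shared
// seed k-mer diagonal voting. Returns for each ordered pair (i -> j, strand of
// j) the best-voted offset of j's start in i coordinates.
// [[Rcpp::export]]
DataFrame cpp_overlap_candidates(CharacterVector contigs, int k, int min_votes,
                                 int rep_cap = 64) {
  if (k > 31) stop("k must be <= 31");
  int n = contigs.size();
  std::vector<std::string> seq(n);
  for (int i = 0; i < n; ++i) seq[i] = as<std::string>(contigs[i]);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> pos;
  for (int i = 0; i < n; ++i)
    kmer_scan(seq[i], k, [&](long p, kmer_t fwd, kmer_t) {
      pos[(uint64_t)fwd].push_back({i, (int)p});
    });

  // votes[(i, j, strand)][diag]
  std::map<std::tuple<int,int,int>, std::unordered_map<long,int>> votes;
  for (int j = 0; j < n; ++j) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? seq[j] : revcomp(seq[j]);
      kmer_scan(q, k, [&](long p, kmer_t fwd, kmer_t) {
        auto it = pos.find((uint64_t)fwd);
        if (it == pos.end()) return;
        if ((int)it->second.size() > rep_cap) return;
        for (auto &tp : it->second) {
          if (tp.first == j) continue;
          long diag = (long)tp.second - (long)p;
          votes[{tp.first, j, strand}][diag]++;
        }
      });
    }
  }
  std::vector<int> oi, oj, ostrand, ovotes;
  std::vector<long> ooff;
  for (auto &kv : votes) {
    long bestd = 0; int bestv = 0;
    for (auto &dv : kv.second)
      if (dv.second > bestv || (dv.second == bestv && dv.first < bestd)) {
        bestv = dv.second; bestd = dv.first;
      }
    if (bestv < min_votes) continue;
    oi.push_back(std::get<0>(kv.first) + 1);
    oj.push_back(std::get<1>(kv.first) + 1);
    ostrand.push_back(std::get<2>(kv.first));
    ooff.push_back(bestd);
    ovotes.push_back(bestv);
  }
  return DataFrame::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                           _["j_strand"] = wrap(ostrand), _["offset"] = wrap(ooff),
                           _["votes"] = wrap(ovotes));
}

// hamming identity between a segment of a and a segment of b of equal length
// [[Rcpp::export]]
double cpp_segment_identity(std::string a, long astart, std::string b,
                            long bstart, long len) {
  if (len <= 0) return 0.0;
  if (astart < 0 || bstart < 0 || astart + len > (long)a.size() ||
      bstart + len > (long)b.size()) return 0.0;
  long m = 0;
  for (long i = 0; i < len; ++i) if (a[astart + i] == b[bstart + i]) ++m;
  return (double)m / (double)len;
}
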