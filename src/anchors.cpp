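#include "core.h"
#include <array>
#include <cctype>
using namespace Rcpp;

// Unique-anchor machinery for whole-assembly comparison: maximal runs of
// seed-mers that are unique in both sequences, merged along diagonals, then
// chained colinearly by weighted longest-increasing-subsequence.

// [[Rcpp::export]]
DataFrame cpp_unique_anchors(std::string a, std::string b, int seed_k, int min_len) {
  if (seed_k > 63) stop("seed_k must be <= 63");
  // map seed-mers of b: position or -2 if duplicated
  std::unordered_map<kmer_t, long, KmerHash> bp;
  kmer_scan(b, seed_k, [&](long i, kmer_t fwd, kmer_t) {
    auto it = bp.find(fwd);
    if (it == bp.end()) bp.emplace(fwd, i); else it->second = -2;
  });
  std::unordered_map<kmer_t, long, KmerHash> ap;
  kmer_scan(a, seed_k, [&](long i, kmer_t fwd, kmer_t) {
    auto it = ap.find(fwd);
    if (it == ap.end()) ap.emplace(fwd, i); else it->second = -2;
  });
  // matches unique in both, keyed by diagonal
  std::vector<std::pair<long,long>> hits; // (apos, bpos)
  for (auto &kv : ap) {
    if (kv.second < 0) continue;
    auto it = bp.find(kv.first);
    if (it == bp.end() || it->second < 0) continue;
    hits.push_back({kv.second, it->second});
  }
  std::sort(hits.begin(), hits.end(),
            [](const std::pair<long,long> &x, const std::pair<long,long> &y) {
              long dx = x.first - x.second, dy = y.first - y.second;
              if (dx != dy) return dx < dy;
              return x.first < y.first;
            });
  std::vector<long> astart, bstart, len;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    long diag = hits[i].first - hits[i].second;
    while (j + 1 < hits.size() &&
           hits[j+1].first - hits[j+1].second == diag &&
           hits[j+1].first <= hits[j].first + seed_k) // overlapping/adjacent run
      ++j;
    long as = hits[i].first, ln = hits[j].first + seed_k - as;
    if (ln >= min_len) {
      astart.push_back(as); bstart.push_back(hits[i].second); len.push_back(ln);
    }
    i = j + 1;
  }
  return DataFrame::create(_["astart"] = wrap(astart), _["bstart"] = wrap(bstart),
                           _["length"] = wrap(len));
}

// weighted LIS chain: anchors must be strictly increasing in both coordinates
// [[Rcpp::export]]
IntegerVector cpp_chain_anchors(NumericVector astart, NumericVector bstart,
                                NumericVector len) {
  int n = astart.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (astart[x] != astart[y]) return astart[x] < astart[y];
    return bstart[x] < bstart[y];
  });
  std::vector<double> best(n);
  std::vector<int> prev(n, -1);
  double gbest = -1; int gend = -1;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    best[i] = len[i];
    for (int jj = 0; jj < ii; ++jj) {
      int j = ord[jj];
      if (astart[j] + len[j] <= astart[i] + len[i] &&
          bstart[j] + len[j] <= bstart[i] + len[i] &&
          astart[j] < astart[i] && bstart[j] < bstart[i]) {
        // penalize offset jumps slightly so alternative placements lose
        double gapa = astart[i] - (astart[j] + len[j]);
        double gapb = bstart[i] - (bstart[j] + len[j]);
        double pen = 0.01 * std::abs(gapa - gapb);
        double cand = best[j] + len[i] - pen;
        if (cand > best[i]) { best[i] = cand; prev[i] = j; }
      }
    }
    if (best[i] > gbest) { gbest = best[i]; gend = i; }
  }
  std::vector<int> chain;
  for (int c = gend; c != -1; c = prev[c]) chain.push_back(c + 1); // 1-based
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// pileup majority polishing
// alignments: per read, 0-based target id/start, strand ('+'/'-'), cigar over
// the oriented query, and the original read sequence.
// [[Rcpp::export]]
List cpp_pileup_polish(CharacterVector contigs, IntegerVector tid,
                       IntegerVector tstart, CharacterVector strand,
                       CharacterVector cigar, CharacterVector seq,
                       int min_depth, double maj_frac) {
  int nc = contigs.size();
  std::vector<std::string> ctg(nc);
  for (int i = 0; i < nc; ++i) ctg[i] = as<std::string>(contigs[i]);
  auto base_idx = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  // counts[contig]: 6 rows (A,C,G,T,del,depth-ins-anchor) x len
  std::vector<std::vector<std::array<int,5>>> counts(nc);
  std::vector<std::unordered_map<long, std::array<int,4>>> ins(nc);
  for (int i = 0; i < nc; ++i)
    counts[i].assign(ctg[i].size(), {0,0,0,0,0});

  int nr = tid.size();
  for (int r = 0; r < nr; ++r) {
    if (tid[r] == NA_INTEGER) continue;
    int t = tid[r] - 1;
    if (t < 0 || t >= nc) continue;
    std::string q = as<std::string>(seq[r]);
    if (as<std::string>(strand[r]) == "-") q = revcomp(q);
    const std::string cg = as<std::string>(cigar[r]);
    long tp = tstart[r];
    long qp = 0;
    size_t p = 0;
    while (p < cg.size()) {
      long n = 0;
      while (p < cg.size() && isdigit(cg[p])) { n = n * 10 + (cg[p] - '0'); ++p; }
      char op = cg[p++];
      if (op == 'M' || op == 'X' || op == '=') {
        for (long x = 0; x < n; ++x) {
          if (tp >= 0 && tp < (long)ctg[t].size()) {
            int b = base_idx(q[qp]);
            if (b >= 0) counts[t][tp][b]++;
          }
          ++tp; ++qp;
        }
      } else if (op == 'D') {
        for (long x = 0; x < n; ++x) {
          if (tp >= 0 && tp < (long)ctg[t].size()) counts[t][tp][4]++;
          ++tp;
        }
      } else if (op == 'I') {
        if (n == 1 && tp > 0 && tp <= (long)ctg[t].size()) {
          int b = base_idx(q[qp]);
          if (b >= 0) ins[t][tp - 1][b]++; // insertion after column tp-1
        }
        qp += n;
      } else if (op == 'S' || op == 'H') {
        if (op == 'S') qp += n;
      }
    }
  }

  int n_sub = 0, n_del = 0, n_ins = 0;
  static const char BASES[4] = {'A','C','G','T'};
  CharacterVector out(nc);
  for (int t = 0; t < nc; ++t) {
    const std::string &s = ctg[t];
    std::string res; res.reserve(s.size() + 16);
    for (long p = 0; p < (long)s.size(); ++p) {
      auto &c = counts[t][p];
      int depth = c[0] + c[1] + c[2] + c[3] + c[4];
      char cur = s[p];
      char put = cur;
      bool drop = false;
      if (depth >= min_depth) {
        if (c[4] > maj_frac * depth) { drop = true; ++n_del; }
        else {
          int bi = base_idx(cur);
          int bestb = -1, bestc = 0;
          for (int b = 0; b < 4; ++b)
            if (c[b] > bestc) { bestc = c[b]; bestb = b; }
          if (bestb >= 0 && bestb != bi && bestc > maj_frac * depth) {
            put = BASES[bestb]; ++n_sub;
          }
        }
      }
      if (!drop) res.push_back(put);
      // single-base insertion after this column
      auto it = ins[t].find(p);
      if (it != ins[t].end() && depth >= min_depth) {
        int bestb = -1, bestc = 0;
        for (int b = 0; b < 4; ++b)
          if (it->second[b] > bestc) { bestc = it->second[b]; bestb = b; }
        if (bestb >= 0 && bestc > maj_frac * depth) {
          res.push_back(BASES[bestb]); ++n_ins;
        }
      }
    }
    out[t] = res;
  }
  return List::create(_["sequence"] = out, _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del);
}
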