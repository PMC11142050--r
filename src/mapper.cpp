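#include "core.h"
using namespace Rcpp;

// Seed-and-extend read mapper.
//
// Index: exact hash of all forward seed_k-mers of every target.
// Query: both orientations are tried; seed hits vote for (target, diagonal);
// top diagonals are verified by ungapped extension, with a glocal DP fallback
// for gapped candidates. Small targets (total length <= exhaustive_limit) fall
// back to full DP over each target, making accept/reject exact in that regime.

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // packed forward seed k-mer (k <= 31) -> (tid, tpos)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> pos;
  size_t n_positions = 0;
};

static void finalize_index(SEXP ptr) {
  SeedIndex *p = (SeedIndex*)R_ExternalPtrAddr(ptr);
  if (p) { delete p; R_ClearExternalPtr(ptr); }
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, CharacterVector names, int k) {
  if (k > 31) stop("seed_k must be <= 31");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->names.push_back(as<std::string>(names[t]));
    idx->seqs.push_back(s);
    if ((int)s.size() < k) continue;
    kmer_scan(s, k, [&](long i, kmer_t fwd, kmer_t) {
      idx->pos[(uint64_t)fwd].push_back({(int)t, (int)i});
      idx->n_positions++;
    });
  }
  SEXP ptr = PROTECT(R_MakeExternalPtr(idx, R_NilValue, R_NilValue));
  R_RegisterCFinalizerEx(ptr, finalize_index, TRUE);
  UNPROTECT(1);
  return ptr;
}

static SeedIndex* get_index(SEXP ptr) {
  SeedIndex *p = (SeedIndex*)R_ExternalPtrAddr(ptr);
  if (!p) stop("seed index pointer is invalid (was it serialized?)");
  return p;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP ptr) {
  SeedIndex *idx = get_index(ptr);
  std::vector<int> lens;
  for (auto &s : idx->seqs) lens.push_back((int)s.size());
  return List::create(_["k"] = idx->k,
                      _["n_targets"] = (int)idx->seqs.size(),
                      _["target_names"] = wrap(idx->names),
                      _["target_lengths"] = wrap(lens),
                      _["n_positions"] = (double)idx->n_positions,
                      _["n_distinct"] = (double)idx->pos.size());
}

struct BestHit {
  bool found = false;
  double score = -1e18;
  int tid = 0, tstart = 0, tend = 0;
  int strand = 0; // 0 = '+', 1 = '-'
  std::string cigar;
  int matches = 0;
};

static bool better(const BestHit &a, const BestHit &b) {
  // higher score, then leftmost tstart, then '+' strand, then lower tid
  if (!b.found) return true;
  if (a.score > b.score + 1e-9) return true;
  if (a.score < b.score - 1e-9) return false;
  if (a.tid != b.tid) return a.tid < b.tid;
  if (a.tstart != b.tstart) return a.tstart < b.tstart;
  return a.strand < b.strand;
}

static void ungapped_candidate(const std::string &q, const SeedIndex *idx,
                               int tid, long diag, int strand, BestHit &best,
                               const Scoring &sc) {
  const std::string &t = idx->seqs[tid];
  const int m = (int)q.size();
  if (diag < 0 || diag + m > (long)t.size()) return;
  int mism = 0, match = 0;
  for (int i = 0; i < m; ++i) {
    if (q[i] == t[diag + i]) ++match; else ++mism;
  }
  double score = match * sc.match + mism * sc.mismatch;
  BestHit h; h.found = true; h.score = score; h.tid = tid;
  h.tstart = (int)diag; h.tend = (int)diag + m; h.strand = strand;
  h.matches = match;
  if (better(h, best)) {
    // build cigar lazily only when adopted
    std::string ops; ops.reserve(m);
    for (int i = 0; i < m; ++i) ops.push_back(q[i] == t[diag + i] ? 'M' : 'X');
    std::string cig;
    for (size_t p = 0; p < ops.size();) {
      size_t p2 = p; while (p2 < ops.size() && ops[p2] == ops[p]) ++p2;
      cig += std::to_string(p2 - p); cig.push_back(ops[p]); p = p2;
    }
    h.cigar = cig;
    best = h;
  }
}

static void dp_candidate(const std::string &q, const SeedIndex *idx,
                         int tid, long diag, int strand, int band,
                         BestHit &best, const Scoring &sc) {
  const std::string &t = idx->seqs[tid];
  const int m = (int)q.size();
  long w0 = diag - band; if (w0 < 0) w0 = 0;
  long w1 = diag + m + band; if (w1 > (long)t.size()) w1 = (long)t.size();
  if (w1 <= w0) return;
  AlnResult r = align_glocal(q, t.substr(w0, w1 - w0), sc);
  if (!r.ok) return;
  BestHit h; h.found = true; h.score = r.score; h.tid = tid;
  h.tstart = (int)(w0 + r.tstart); h.tend = (int)(w0 + r.tend);
  h.strand = strand; h.cigar = r.cigar; h.matches = r.matches;
  if (better(h, best)) best = h;
}

static void full_dp_target(const std::string &q, const SeedIndex *idx,
                           int tid, int strand, BestHit &best, const Scoring &sc) {
  AlnResult r = align_glocal(q, idx->seqs[tid], sc);
  if (!r.ok) return;
  BestHit h; h.found = true; h.score = r.score; h.tid = tid;
  h.tstart = r.tstart; h.tend = r.tend; h.strand = strand;
  h.cigar = r.cigar; h.matches = r.matches;
  if (better(h, best)) best = h;
}

// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector queries, SEXP ptr,
                        double match, double mismatch, double gap_open,
                        double gap_ext, double min_score_per_base,
                        int max_diags = 4, int rep_cap = 32,
                        double exhaustive_limit = 4000) {
  SeedIndex *idx = get_index(ptr);
  const int k = idx->k;
  Scoring sc{match, mismatch, gap_open, gap_ext};
  size_t total_t = 0;
  for (auto &s : idx->seqs) total_t += s.size();
  const bool exhaustive = (double)total_t <= exhaustive_limit;

  const R_xlen_t n = queries.size();
  IntegerVector out_tid(n), out_tstart(n), out_tend(n), out_matches(n);
  CharacterVector out_strand(n), out_cigar(n);
  NumericVector out_score(n);
  LogicalVector out_mapped(n);

  std::vector<uint64_t> votekeys;

  for (R_xlen_t qi = 0; qi < n; ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    const int m = (int)fwd.size();
    double thresh = min_score_per_base * m;
    BestHit best;
    // max gap length affordable within threshold, for DP band
    int band = 8;
    if (gap_ext < 0) {
      double budget = -thresh + gap_open;
      int g = (int)std::floor(budget / (-gap_ext));
      if (g < 2) g = 2; if (g > 64) g = 64;
      band = g;
    }
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp(fwd);
      if (exhaustive) {
        for (int tid = 0; tid < (int)idx->seqs.size(); ++tid)
          full_dp_target(q, idx, tid, strand, best, sc);
        continue;
      }
      if (m < k) continue;
      votekeys.clear();
      kmer_scan(q, k, [&](long i, kmer_t fwd, kmer_t) {
        auto it = idx->pos.find((uint64_t)fwd);
        if (it == idx->pos.end()) return;
        if ((int)it->second.size() > rep_cap) return;
        for (auto &tp : it->second) {
          long diag = (long)tp.second - i;
          if (diag < -(long)band) diag = -(long)band;
          votekeys.push_back(((uint64_t)tp.first << 40) ^
                             (uint64_t)(diag + (1L << 34)));
        }
      });
      if (votekeys.empty()) continue;
      std::sort(votekeys.begin(), votekeys.end());
      std::vector<std::pair<int, uint64_t>> ranked; // (votes, key)
      for (size_t p = 0; p < votekeys.size();) {
        size_t p2 = p;
        while (p2 < votekeys.size() && votekeys[p2] == votekeys[p]) ++p2;
        ranked.push_back({(int)(p2 - p), votekeys[p]});
        p = p2;
      }
      std::sort(ranked.begin(), ranked.end(),
                [](const std::pair<int,uint64_t> &a, const std::pair<int,uint64_t> &b) {
                  if (a.first != b.first) return a.first > b.first;
                  return a.second < b.second;
                });
      // merge nearby diagonals: keep top distinct candidates
      std::vector<std::pair<int,long>> cands; // (tid, diag)
      std::vector<int> cand_votes;
      for (auto &rk : ranked) {
        int tid = (int)(rk.second >> 40);
        long diag = (long)(rk.second & ((1ULL << 40) - 1)) - (1L << 34);
        bool dup = false;
        for (auto &c : cands)
          if (c.first == tid && std::llabs(c.second - diag) <= band) { dup = true; break; }
        if (!dup) { cands.push_back({tid, diag}); cand_votes.push_back(rk.first); }
        if ((int)cands.size() >= max_diags) break;
      }
      for (auto &c : cands)
        ungapped_candidate(q, idx, c.first, c.second, strand, best, sc);
      if (!(best.found && best.score >= thresh - 1e-9)) {
        // gapped rescue only where seeds give real support (an indel read
        // keeps a long exact stretch, hence many co-diagonal seed hits)
        for (size_t ci = 0; ci < cands.size(); ++ci)
          if (cand_votes[ci] >= 5)
            dp_candidate(q, idx, cands[ci].first, cands[ci].second, strand,
                         band, best, sc);
      }
    }
    if (best.found && best.score >= thresh - 1e-9) {
      out_mapped[qi] = true;
      out_tid[qi] = best.tid + 1;
      out_tstart[qi] = best.tstart;
      out_tend[qi] = best.tend;
      out_strand[qi] = best.strand == 0 ? "+" : "-";
      out_score[qi] = best.score;
      out_cigar[qi] = best.cigar;
      out_matches[qi] = best.matches;
    } else {
      out_mapped[qi] = false;
      out_tid[qi] = NA_INTEGER; out_tstart[qi] = NA_INTEGER;
      out_tend[qi] = NA_INTEGER; out_matches[qi] = NA_INTEGER;
      out_strand[qi] = NA_STRING; out_cigar[qi] = NA_STRING;
      out_score[qi] = NA_REAL;
    }
  }
  return DataFrame::create(_["mapped"] = out_mapped, _["tid"] = out_tid,
                           _["tstart"] = out_tstart, _["tend"] = out_tend,
                           _["strand"] = out_strand, _["score"] = out_score,
                           _["matches"] = out_matches, _["cigar"] = out_cigar,
                           _["stringsAsFactors"] = false);
}
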