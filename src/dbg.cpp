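#include "core.h"
using namespace Rcpp;

// Bidirected de Bruijn graph over canonical k-mers (k odd <= 63, so no k-mer
// is its own reverse complement). K-mers are 2-bit packed. Nodes carry
// occurrence coverage; edges are implicit (k-1 overlap, queried against the
// hash). Supports coverage filtering, tip clipping, bubble popping and
// unitig extraction.

struct DBG {
  int k;
  std::unordered_map<kmer_t, int, KmerHash> id; // canonical kmer -> node id
  std::vector<kmer_t> kmer;
  std::vector<float> cov;
  std::vector<char> alive;
};

static void finalize_dbg(SEXP ptr) {
  DBG *p = (DBG*)R_ExternalPtrAddr(ptr);
  if (p) { delete p; R_ClearExternalPtr(ptr); }
}

static DBG* get_dbg(SEXP ptr) {
  DBG *p = (DBG*)R_ExternalPtrAddr(ptr);
  if (!p) stop("de Bruijn graph pointer is invalid");
  return p;
}

// oriented node: (id, o). o == 0 spelled as stored (canonical), o == 1 as rc.
struct ONode { int id; int o; };
static inline bool same(const ONode &a, const ONode &b) {
  return a.id == b.id && a.o == b.o;
}

static inline kmer_t spell_packed(const DBG *g, int id, int o) {
  return o == 0 ? g->kmer[id] : kmer_rc(g->kmer[id], g->k);
}

static int succ_nodes(const DBG *g, const ONode &u, ONode out[4]) {
  kmer_t s = spell_packed(g, u.id, u.o);
  kmer_t mask = kmer_mask(g->k);
  int n = 0;
  for (int b = 0; b < 4; ++b) {
    kmer_t t = ((s << 2) | (kmer_t)b) & mask;
    kmer_t tr = kmer_rc(t, g->k);
    kmer_t ct = t < tr ? t : tr;
    auto it = g->id.find(ct);
    if (it == g->id.end() || !g->alive[it->second]) continue;
    out[n].id = it->second;
    out[n].o = (t == ct) ? 0 : 1;
    ++n;
  }
  return n;
}

static int pred_nodes(const DBG *g, const ONode &u, ONode out[4]) {
  ONode r{u.id, 1 - u.o};
  int n = succ_nodes(g, r, out);
  for (int i = 0; i < n; ++i) out[i].o = 1 - out[i].o;
  return n;
}

// [[Rcpp::export]]
SEXP cpp_dbg_build(CharacterVector reads, int k) {
  if (k % 2 == 0) stop("k must be odd");
  if (k > 63) stop("k must be <= 63");
  DBG *g = new DBG();
  g->k = k;
  bool any = false;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *cs = CHAR(STRING_ELT(reads, r));
    std::string s(cs);
    if ((int)s.size() < k) continue;
    any = true;
    kmer_scan(s, k, [&](long, kmer_t fwd, kmer_t rev) {
      kmer_t c = fwd < rev ? fwd : rev;
      auto it = g->id.find(c);
      if (it == g->id.end()) {
        int nid = (int)g->kmer.size();
        g->id.emplace(c, nid);
        g->kmer.push_back(c);
        g->cov.push_back(1.0f);
        g->alive.push_back(1);
      } else g->cov[it->second] += 1.0f;
    });
  }
  if (!any) { delete g; stop("all reads are shorter than k; use a smaller k"); }
  SEXP ptr = PROTECT(R_MakeExternalPtr(g, R_NilValue, R_NilValue));
  R_RegisterCFinalizerEx(ptr, finalize_dbg, TRUE);
  UNPROTECT(1);
  return ptr;
}

// [[Rcpp::export]]
List cpp_dbg_stats(SEXP ptr) {
  DBG *g = get_dbg(ptr);
  int n = 0;
  std::vector<double> cov;
  for (size_t i = 0; i < g->kmer.size(); ++i)
    if (g->alive[i]) { ++n; cov.push_back(g->cov[i]); }
  return List::create(_["k"] = g->k, _["n_nodes"] = n, _["coverage"] = wrap(cov));
}

// [[Rcpp::export]]
DataFrame cpp_dbg_nodes(SEXP ptr) {
  DBG *g = get_dbg(ptr);
  std::vector<std::string> km;
  std::vector<double> cov;
  for (size_t i = 0; i < g->kmer.size(); ++i)
    if (g->alive[i]) {
      km.push_back(kmer_decode(g->kmer[i], g->k));
      cov.push_back(g->cov[i]);
    }
  return DataFrame::create(_["kmer"] = wrap(km), _["coverage"] = wrap(cov),
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
int cpp_dbg_drop_low_cov(SEXP ptr, double cutoff) {
  DBG *g = get_dbg(ptr);
  int dropped = 0;
  for (size_t i = 0; i < g->kmer.size(); ++i)
    if (g->alive[i] && g->cov[i] < cutoff) { g->alive[i] = 0; ++dropped; }
  return dropped;
}

// walk forward from u while the path is linear; stops before branches
static std::vector<ONode> walk_unitig(const DBG *g, ONode u, int max_nodes) {
  std::vector<ONode> path{u};
  ONode sbuf[4], pbuf[4];
  while ((int)path.size() < max_nodes) {
    if (succ_nodes(g, path.back(), sbuf) != 1) break;
    if (pred_nodes(g, sbuf[0], pbuf) != 1) break;
    if (sbuf[0].id == path.front().id) break; // cycle closure
    path.push_back(sbuf[0]);
  }
  return path;
}

// [[Rcpp::export]]
int cpp_dbg_clip_tips(SEXP ptr, int tip_len) {
  DBG *g = get_dbg(ptr);
  int clipped = 0;
  ONode sbuf[4], pbuf[4];
  for (size_t i = 0; i < g->kmer.size(); ++i) {
    if (!g->alive[i]) continue;
    ONode u{(int)i, 0};
    int np = pred_nodes(g, u, pbuf);
    int ns = succ_nodes(g, u, sbuf);
    ONode start; bool is_end = false;
    if (np == 0 && ns > 0) { start = u; is_end = true; }
    else if (ns == 0 && np > 0) { start = {(int)i, 1}; is_end = true; }
    if (!is_end) continue;
    auto path = walk_unitig(g, start, tip_len);
    int bp = g->k + (int)path.size() - 1;
    if (bp >= tip_len) continue;
    int ns2 = succ_nodes(g, path.back(), sbuf);
    if (ns2 == 0) continue; // isolated short unitig: keep
    bool attached = false;
    for (int x = 0; x < ns2; ++x)
      if (pred_nodes(g, sbuf[x], pbuf) >= 2) attached = true;
    if (!attached && ns2 < 2) continue;
    for (auto &nd : path) g->alive[nd.id] = 0;
    ++clipped;
  }
  return clipped;
}

static double seq_identity(const std::string &a, const std::string &b) {
  if (a.empty() || b.empty()) return 0.0;
  if ((double)a.size() * (double)b.size() > 4e6) return 0.0;
  Scoring sc{0, -1, -1, -1};
  AlnResult r = align_global(a, b, sc);
  size_t mx = std::max(a.size(), b.size());
  return (double)r.matches / (double)mx;
}

static std::string spell_path(const DBG *g, const std::vector<ONode> &path) {
  std::string s = kmer_decode(spell_packed(g, path[0].id, path[0].o), g->k);
  for (size_t i = 1; i < path.size(); ++i) {
    kmer_t x = spell_packed(g, path[i].id, path[i].o);
    static const char B[4] = {'A', 'C', 'G', 'T'};
    s.push_back(B[(int)(x & 3)]);
  }
  return s;
}

// [[Rcpp::export]]
int cpp_dbg_pop_bubbles(SEXP ptr, double ident, int max_bp,
                        double max_ratio = 0.5, double low_cov_floor = 5.0,
                        double expected_cov = -1.0) {
  DBG *g = get_dbg(ptr);
  int popped = 0;
  int max_nodes = max_bp;
  ONode sbuf[4], na[4], nb[4];
  for (size_t i = 0; i < g->kmer.size(); ++i) {
    if (!g->alive[i]) continue;
    for (int o = 0; o < 2; ++o) {
      ONode u{(int)i, o};
      if (succ_nodes(g, u, sbuf) != 2) continue;
      std::vector<ONode> pa = walk_unitig(g, sbuf[0], max_nodes);
      std::vector<ONode> pb = walk_unitig(g, sbuf[1], max_nodes);
      if (succ_nodes(g, pa.back(), na) != 1) continue;
      if (succ_nodes(g, pb.back(), nb) != 1) continue;
      if (!same(na[0], nb[0])) continue;
      bool disjoint = true;
      for (auto &x : pa) { for (auto &y : pb) if (x.id == y.id) { disjoint = false; break; } if (!disjoint) break; }
      if (!disjoint) continue;
      std::string sa = spell_path(g, pa), sb = spell_path(g, pb);
      if (seq_identity(sa, sb) < ident) continue;
      double ca = 0, cb = 0;
      for (auto &x : pa) ca += g->cov[x.id];
      for (auto &x : pb) cb += g->cov[x.id];
      ca /= pa.size(); cb /= pb.size();
      // pop noise and heterozygous bubbles, keep repeat-copy bubbles:
      // het branches run at ~half the graph-wide expected coverage, while
      // balanced branches at full expected coverage are genuine two-copy
      // sequence (near-identical tandem units) whose collapse would weld
      // repeat copies into false contractions
      double mn = std::min(ca, cb), mx = std::max(ca, cb);
      bool noise = (mn <= low_cov_floor) || (mn <= max_ratio * mx);
      bool het_like = expected_cov > 0 && mx < 0.75 * expected_cov;
      if (!noise && !het_like) continue;
      const std::vector<ONode> &loser = (ca >= cb) ? pb : pa;
      for (auto &x : loser) g->alive[x.id] = 0;
      ++popped;
      break;
    }
  }
  return popped;
}

// [[Rcpp::export]]
List cpp_dbg_contigs(SEXP ptr, int min_len) {
  DBG *g = get_dbg(ptr);
  std::vector<std::string> seqs;
  std::vector<double> covs;
  std::vector<char> visited(g->kmer.size(), 0);
  ONode sbuf[4], pbuf[4];

  auto is_start = [&](const ONode &u) {
    int np = pred_nodes(g, u, pbuf);
    if (np != 1) return true;
    ONode p = pbuf[0];
    return succ_nodes(g, p, sbuf) != 1;
  };

  auto emit = [&](const std::vector<ONode> &path) {
    for (auto &nd : path) visited[nd.id] = 1;
    std::string s = spell_path(g, path);
    if ((int)s.size() < min_len) return;
    double c = 0;
    for (auto &nd : path) c += g->cov[nd.id];
    seqs.push_back(s);
    covs.push_back(c / path.size());
  };

  for (size_t i = 0; i < g->kmer.size(); ++i) {
    if (!g->alive[i] || visited[i]) continue;
    for (int o = 0; o < 2; ++o) {
      ONode u{(int)i, o};
      if (!is_start(u)) continue;
      std::vector<ONode> path{u};
      while (true) {
        if (succ_nodes(g, path.back(), sbuf) != 1) break;
        if (pred_nodes(g, sbuf[0], pbuf) != 1) break;
        if (visited[sbuf[0].id]) break;
        bool seen = false;
        for (auto &nd : path) if (nd.id == sbuf[0].id) { seen = true; break; }
        if (seen) break;
        path.push_back(sbuf[0]);
      }
      emit(path);
      break;
    }
  }
  // leftover: pure cycles
  for (size_t i = 0; i < g->kmer.size(); ++i) {
    if (!g->alive[i] || visited[i]) continue;
    ONode u{(int)i, 0};
    std::vector<ONode> path{u};
    visited[i] = 1;
    while (true) {
      if (succ_nodes(g, path.back(), sbuf) != 1) break;
      if (visited[sbuf[0].id]) break;
      path.push_back(sbuf[0]);
      visited[sbuf[0].id] = 1;
    }
    emit(path);
  }
  return List::create(_["sequence"] = wrap(seqs), _["coverage"] = wrap(covs));
}
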