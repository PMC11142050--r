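#include "core.h"
using namespace Rcpp;

// Affine-gap dynamic programming with traceback.
// glocal: query consumed end-to-end, target prefix/suffix free.
// global: both consumed end-to-end.
//
// Three-state DP (H = match/mismatch, E = gap in query (D), F = gap in
// target (I)). Gap of length g costs gap_open + g * gap_ext.

static const double NEG = -1e18;

static AlnResult dp_align(const std::string &q, const std::string &t,
                          const Scoring &sc, bool free_t_ends) {
  const int m = (int)q.size(), n = (int)t.size();
  AlnResult res; res.ok = false; res.score = NEG; res.matches = 0;
  if (m == 0 || n == 0) {
    if (m == 0 && free_t_ends) { // empty query trivially aligns nowhere
      res.ok = true; res.score = 0; res.tstart = 0; res.tend = 0; res.cigar = "";
      return res;
    }
    if (m == 0 && n == 0) { res.ok = true; res.score = 0; res.tstart = 0; res.tend = 0; return res; }
    if (m == 0) { // global: all deletions
      res.ok = true; res.score = sc.gap_open + n * sc.gap_ext;
      res.tstart = 0; res.tend = n; res.cigar = std::to_string(n) + "D";
      return res;
    }
    // n == 0: all insertions
    res.ok = true; res.score = sc.gap_open + m * sc.gap_ext;
    res.tstart = 0; res.tend = 0; res.cigar = std::to_string(m) + "I";
    return res;
  }

  std::vector<double> H((size_t)(m + 1) * (n + 1)), E(H.size()), F(H.size());
  // traceback: 2 bits per state origin packed in a byte per cell
  std::vector<unsigned char> tbH(H.size()), tbE(H.size()), tbF(H.size());
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  H[at(0,0)] = 0; E[at(0,0)] = NEG; F[at(0,0)] = NEG;
  for (int j = 1; j <= n; ++j) {
    E[at(0,j)] = free_t_ends ? NEG : sc.gap_open + j * sc.gap_ext;
    H[at(0,j)] = free_t_ends ? 0 : E[at(0,j)];
    F[at(0,j)] = NEG;
    tbH[at(0,j)] = free_t_ends ? 3 : 1; // 3 = start, 1 = from E
  }
  for (int i = 1; i <= m; ++i) {
    F[at(i,0)] = sc.gap_open + i * sc.gap_ext;
    H[at(i,0)] = F[at(i,0)];
    E[at(i,0)] = NEG;
    tbH[at(i,0)] = 2; // from F
    tbF[at(i,0)] = 1; // extend
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t c = at(i,j), up = at(i-1,j), lf = at(i,j-1), dg = at(i-1,j-1);
      // E: gap in query (consume target base j) => D op
      double e_open = H[lf] + sc.gap_open + sc.gap_ext;
      double e_ext  = E[lf] + sc.gap_ext;
      if (e_open >= e_ext) { E[c] = e_open; tbE[c] = 0; } else { E[c] = e_ext; tbE[c] = 1; }
      // F: gap in target (consume query base i) => I op
      double f_open = H[up] + sc.gap_open + sc.gap_ext;
      double f_ext  = F[up] + sc.gap_ext;
      if (f_open >= f_ext) { F[c] = f_open; tbF[c] = 0; } else { F[c] = f_ext; tbF[c] = 1; }
      // H
      double diag = H[dg] + (q[i-1] == t[j-1] ? sc.match : sc.mismatch);
      double best = diag; unsigned char tb = 0;
      if (E[c] > best) { best = E[c]; tb = 1; }
      if (F[c] > best) { best = F[c]; tb = 2; }
      H[c] = best; tbH[c] = tb;
    }
  }

  int endj = n;
  double best = H[at(m,n)];
  if (free_t_ends) { // max over final row, leftmost tie
    best = NEG;
    for (int j = 0; j <= n; ++j) if (H[at(m,j)] > best) best = H[at(m,j)];
    for (int j = 0; j <= n; ++j) if (H[at(m,j)] >= best - 1e-12) { endj = j; break; }
  }

  // traceback
  std::string ops; ops.reserve(m + n);
  int i = m, j = endj, state = 0; // 0=H,1=E,2=F
  int matches = 0;
  while (i > 0 || (state != 0) || (j > 0 && !free_t_ends)) {
    if (state == 0) {
      unsigned char tb = tbH[at(i,j)];
      if (i == 0 && free_t_ends) break;
      if (tb == 3) break;
      if (tb == 0) {
        if (i == 0 || j == 0) { // boundary came from gap inits
          if (j == 0 && i > 0) { state = 2; continue; }
          if (i == 0 && j > 0) { state = 1; continue; }
          break;
        }
        bool eq = (q[i-1] == t[j-1]);
        ops.push_back(eq ? 'M' : 'X');
        if (eq) ++matches;
        --i; --j;
      } else if (tb == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      unsigned char tb = tbE[at(i,j)];
      --j;
      if (tb == 0) state = 0;
      if (j == 0 && state == 1) state = 0;
    } else {
      ops.push_back('I');
      unsigned char tb = tbF[at(i,j)];
      --i;
      if (tb == 0) state = 0;
      if (i == 0 && state == 2) state = 0;
    }
  }
  int startj = j;
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t p2 = p;
    while (p2 < ops.size() && ops[p2] == ops[p]) ++p2;
    cig += std::to_string(p2 - p); cig.push_back(ops[p]);
    p = p2;
  }

  res.ok = true; res.score = best; res.tstart = startj; res.tend = endj;
  res.cigar = cig; res.matches = matches;
  return res;
}

AlnResult align_glocal(const std::string &q, const std::string &t, const Scoring &sc) {
  return dp_align(q, t, sc, true);
}
AlnResult align_global(const std::string &a, const std::string &b, const Scoring &sc) {
  return dp_align(a, b, sc, false);
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, double match, double mismatch,
                      double gap_open, double gap_ext) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  AlnResult r = align_global(a, b, sc);
  return List::create(_["score"] = r.score, _["cigar"] = r.cigar,
                      _["matches"] = r.matches);
}

// [[Rcpp::export]]
List cpp_align_glocal(std::string q, std::string t, double match, double mismatch,
                      double gap_open, double gap_ext) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  AlnResult r = align_glocal(q, t, sc);
  return List::create(_["score"] = r.score, _["cigar"] = r.cigar,
                      _["tstart"] = r.tstart, _["tend"] = r.tend,
                      _["matches"] = r.matches);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
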