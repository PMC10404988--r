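#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e18;

// State codes used in tracebacks: 0 = M (diagonal), 1 = X (gap in b / "up",
// consumes a), 2 = Y (gap in a / "left", consumes b).  Tie preference is
// always M, then X, then Y, giving a deterministic traceback.

static inline int best3(double m, double x, double y, double &out) {
  // preference M > X > Y on ties
  if (m >= x && m >= y) { out = m; return 0; }
  if (x >= y) { out = x; return 1; }
  out = y; return 2;
}

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// Gap of length L costs gap_open + L * gap_extend.
// If band > 0 only cells with drift(j - i) within [lo - band, hi + band]
// are filled, where [lo, hi] covers the corner-to-corner drift.
// "interior" reports whether the optimal traceback stayed strictly inside
// the band (always true for band <= 0, i.e. full matrix).
// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int band) {
  int n = a.size(), m = b.size();
  int lo = std::min(0, m - n), hi = std::max(0, m - n);
  bool banded = band > 0 && (band < n + m);
  int blo = banded ? lo - band : -(n + 2);
  int bhi = banded ? hi + band : (m + 2);

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i)
    if (-i >= blo) X(i, 0) = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j)
    if (j <= bhi) Y(0, j) = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i + blo), jmax = std::min(m, i + bhi);
    for (int j = jmin; j <= jmax; ++j) {
      double diagbest;
      best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), diagbest);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (diagbest > NEG / 2) M(i, j) = diagbest + s;
      // X: a_i aligned to gap
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - (gap_open + gap_extend);
      double xe = X(i - 1, j) - gap_extend;
      double xb = std::max(xo, xe);
      if (xb > NEG / 2) X(i, j) = xb;
      // Y: b_j aligned to gap
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - (gap_open + gap_extend);
      double ye = Y(i, j - 1) - gap_extend;
      double yb = std::max(yo, ye);
      if (yb > NEG / 2) Y(i, j) = yb;
    }
  }

  double score;
  int state = best3(M(n, m), X(n, m), Y(n, m), score);

  // traceback
  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m;
  int matches = 0, columns = 0;
  bool interior = true;
  while (i > 0 || j > 0) {
    if (banded) {
      int drift = j - i;
      if (drift <= blo || drift >= bhi) interior = false;
    }
    if (state == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      ++columns;
      double prev; int ps = best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), prev);
      --i; --j; state = ps;
    } else if (state == 1) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      ++columns;
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - (gap_open + gap_extend);
      double xe = X(i - 1, j) - gap_extend;
      int ps;
      if (xo >= xe) ps = (M(i - 1, j) >= Y(i - 1, j)) ? 0 : 2; else ps = 1;
      --i; state = ps;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      ++columns;
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - (gap_open + gap_extend);
      double ye = Y(i, j - 1) - gap_extend;
      int ps;
      if (yo >= ye) ps = (M(i, j - 1) >= X(i, j - 1)) ? 0 : 1; else ps = 2;
      --j; state = ps;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(
    _["score"] = score,
    _["matches"] = matches,
    _["columns"] = columns,
    _["identity"] = columns > 0 ? (double)matches / columns : 1.0,
    _["a_aln"] = aa,
    _["b_aln"] = bb,
    _["interior"] = interior);
}

// Fit ("glocal") alignment: the reference must be consumed end to end,
// read overhangs on either side are free.  Used for V9 extraction where
// the full-span rule requires the reference's first and last base to be
// aligned to read bases (not gapped out); `full_span` reports that.
// Rows i index the read, columns j the reference.
// [[Rcpp::export]]
List cpp_align_fit(std::string read, std::string ref,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  int n = read.size(), m = ref.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  for (int i = 0; i <= n; ++i) M(i, 0) = 0.0;          // free read prefix
  for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diagbest;
      best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), diagbest);
      double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      if (diagbest > NEG / 2) M(i, j) = diagbest + s;
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - (gap_open + gap_extend);
      double xe = X(i - 1, j) - gap_extend;
      double xb = std::max(xo, xe);
      if (xb > NEG / 2) X(i, j) = xb;
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - (gap_open + gap_extend);
      double ye = Y(i, j - 1) - gap_extend;
      double yb = std::max(yo, ye);
      if (yb > NEG / 2) Y(i, j) = yb;
    }
  }

  // free read suffix: best over rows in the last column
  double score = NEG;
  int iend = 0, state = 0;
  for (int i = 0; i <= n; ++i) {
    double sc; int st = best3(M(i, m), X(i, m), Y(i, m), sc);
    // X at (i, m) trails read bases against gaps after the reference is
    // consumed; a free suffix is always at least as good, so skip X ends.
    if (st == 1) { sc = std::max(M(i, m), Y(i, m)); st = (M(i, m) >= Y(i, m)) ? 0 : 2; }
    if (sc > score) { score = sc; iend = i; state = st; }
  }
  if (score <= NEG / 2)
    return List::create(_["score"] = NA_REAL);

  bool last_diag = (state == 0);
  int i = iend, j = m;
  int matches = 0, columns = 0;
  int first_state = state;
  while (j > 0) {
    first_state = state;
    if (state == 0) {
      if (read[i - 1] == ref[j - 1]) ++matches;
      ++columns;
      double prev; int ps = best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), prev);
      --i; --j; state = ps;
    } else if (state == 1) {
      ++columns;
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - (gap_open + gap_extend);
      double xe = X(i - 1, j) - gap_extend;
      int ps;
      if (xo >= xe) ps = (M(i - 1, j) >= Y(i - 1, j)) ? 0 : 2; else ps = 1;
      --i; state = ps;
    } else {
      ++columns;
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - (gap_open + gap_extend);
      double ye = Y(i, j - 1) - gap_extend;
      int ps;
      if (yo >= ye) ps = (M(i, j - 1) >= X(i, j - 1)) ? 0 : 1; else ps = 2;
      --j; state = ps;
    }
  }
  bool first_diag = (first_state == 0);

  return List::create(
    _["score"] = score,
    _["matches"] = matches,
    _["columns"] = columns,
    _["identity"] = columns > 0 ? (double)matches / columns : 0.0,
    _["read_start"] = i,       // 0-based start of aligned read interval
    _["read_end"] = iend,      // 0-based exclusive end
    _["full_span"] = (first_diag && last_diag));
}

static int edit_bounded_one(const std::string &a, const std::string &b, int maxd) {
  int n = a.size(), m = b.size();
  if (std::abs(n - m) > maxd) return maxd + 1;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i - maxd), jmax = std::min(m, i + maxd);
    int big = maxd + 1;
    cur[0] = i;
    if (jmin > 1) cur[jmin - 1] = big;
    int rowmin = (jmin == 1) ? cur[0] : big;
    for (int j = jmin; j <= jmax; ++j) {
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int v = std::min(std::min(del, ins), sub);
      if (v > big) v = big;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (jmax < m) cur[jmax + 1] = big;  // guard cell for next row's reads
    if (rowmin > maxd) return maxd + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[m], maxd + 1);
}

// Banded Levenshtein distance capped at maxd + 1.
// [[Rcpp::export]]
int cpp_edit_bounded(std::string a, std::string b, int maxd) {
  return edit_bounded_one(a, b, maxd);
}

// Cross matrix of capped edit distances (rows = a, cols = b).
// [[Rcpp::export]]
IntegerMatrix cpp_edit_cross(CharacterVector a, CharacterVector b, int maxd) {
  IntegerMatrix out(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i) {
    std::string ai = as<std::string>(a[i]);
    for (int j = 0; j < b.size(); ++j)
      out(i, j) = edit_bounded_one(ai, as<std::string>(b[j]), maxd);
  }
  return out;
}

// All pairs of unique sequences at Levenshtein distance <= 1, found by
// the deletion-signature trick: each sequence is keyed by itself and by
// every single-deletion variant; candidate pairs share a key and are
// verified with the bounded edit distance.  Returns a 2-column 1-based
// index matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_d1_pairs(CharacterVector seqs) {
  int n = seqs.size();
  std::unordered_map<std::string, std::vector<int> > buckets;
  buckets.reserve(n * 8);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    buckets[s].push_back(i);
    for (size_t p = 0; p < s.size(); ++p) {
      std::string d = s.substr(0, p) + s.substr(p + 1);
      buckets[d].push_back(i);
    }
  }
  std::set<std::pair<int, int> > pairs;
  for (auto &kv : buckets) {
    std::vector<int> &v = kv.second;
    if (v.size() < 2) continue;
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        pairs.insert(std::make_pair(v[x], v[y]));
  }
  std::vector<int> r1, r2;
  for (auto &pr : pairs) {
    std::string a = as<std::string>(seqs[pr.first]);
    std::string b = as<std::string>(seqs[pr.second]);
    if (edit_bounded_one(a, b, 1) <= 1) {
      r1.push_back(pr.first + 1);
      r2.push_back(pr.second + 1);
    }
  }
  IntegerMatrix out(r1.size(), 2);
  for (size_t k = 0; k < r1.size(); ++k) { out(k, 0) = r1[k]; out(k, 1) = r2[k]; }
  return out;
}

static inline int iupac_mask(char c) {
  switch (toupper(c)) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

static inline int literal_mask(char c) {
  // subject bases get no credit for degeneracy: only A/C/G/T can match
  switch (toupper(c)) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default: return 0;
  }
}

// IUPAC-aware mismatch count over an ungapped window: the primer's
// degenerate bases match any of their expansions; degenerate bases in the
// subject never match.  Windows must have equal length.
// [[Rcpp::export]]
int cpp_iupac_mm(std::string window, std::string primer) {
  if (window.size() != primer.size()) stop("window/primer length mismatch");
  int mm = 0;
  for (size_t k = 0; k < primer.size(); ++k)
    if (!(iupac_mask(primer[k]) & literal_mask(window[k]))) ++mm;
  return mm;
}

// Scan every primer-length window of `seq`; report 0-based starts with
// IUPAC-aware Hamming distance <= max_mm, sorted by mismatch count then
// leftmost position.
// [[Rcpp::export]]
DataFrame cpp_primer_scan(std::string seq, std::string primer, int max_mm) {
  int n = seq.size(), p = primer.size();
  std::vector<int> starts, mms;
  if (p <= n) {
    std::vector<int> pmask(p);
    for (int k = 0; k < p; ++k) pmask[k] = iupac_mask(primer[k]);
    for (int s = 0; s + p <= n; ++s) {
      int mm = 0;
      for (int k = 0; k < p && mm <= max_mm; ++k)
        if (!(pmask[k] & literal_mask(seq[s + k]))) ++mm;
      if (mm <= max_mm) { starts.push_back(s); mms.push_back(mm); }
    }
  }
  // stable sort by mismatches (starts already leftmost-first)
  std::vector<int> idx(starts.size());
  for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int x, int y) { return mms[x] < mms[y]; });
  IntegerVector so(idx.size()), mo(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) { so[k] = starts[idx[k]]; mo[k] = mms[idx[k]]; }
  return DataFrame::create(_["start"] = so, _["mismatches"] = mo);
}

// Longest common prefix and suffix lengths of a child sequence against
// each candidate parent (bimera reconstruction test).
// [[Rcpp::export]]
IntegerMatrix cpp_prefix_suffix(std::string child, CharacterVector parents) {
  int n = parents.size(), L = child.size();
  IntegerMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    std::string p = as<std::string>(parents[k]);
    int lim = std::min((int)p.size(), L);
    int lcp = 0;
    while (lcp < lim && child[lcp] == p[lcp]) ++lcp;
    int lcs = 0;
    while (lcs < lim && child[L - 1 - lcs] == p[p.size() - 1 - lcs]) ++lcs;
    out(k, 0) = lcp;
    out(k, 1) = lcs;
  }
  return out;
}
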