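#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Scoring: N never matches anything (incl. N); gaps are linear.
static inline double subscore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// Needleman-Wunsch global alignment, linear gap penalty.
// Traceback ties broken diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // ptr: 0 = diag, 1 = up (consume a), 2 = left (consume b)
  std::vector<unsigned char> ptr((n + 1) * (m + 1));
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; ptr[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    ptr[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + subscore(a[i - 1], b[j - 1], match, mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      if (d >= u && d >= l)      { cur[j] = d; ptr[i * (m + 1) + j] = 0; }
      else if (u >= l)           { cur[j] = u; ptr[i * (m + 1) + j] = 1; }
      else                       { cur[j] = l; ptr[i * (m + 1) + j] = 2; }
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[i * (m + 1) + j];
    if (p == 0)      { ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j; }
    else if (p == 1) { ga.push_back(a[i - 1]); gb.push_back('-'); --i; }
    else             { ga.push_back('-'); gb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = score);
}

// Smith-Waterman local alignment, linear gap penalty.
// Best cell ties resolved to the smallest (i, j); traceback diag > up > left.
// Returns 0-based half-open matched intervals on both inputs.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  // ptr: 0 diag, 1 up, 2 left, 3 stop
  std::vector<unsigned char> ptr((n + 1) * (m + 1), 3);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + subscore(a[i - 1], b[j - 1], match, mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double s; unsigned char p;
      if (d >= u && d >= l) { s = d; p = 0; }
      else if (u >= l)      { s = u; p = 1; }
      else                  { s = l; p = 2; }
      if (s <= 0.0) { s = 0.0; p = 3; }
      cur[j] = s; ptr[i * (m + 1) + j] = p;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  std::string ga, gb;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char p = ptr[i * (m + 1) + j];
    if (p == 3) break;
    if (p == 0)      { ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j; }
    else if (p == 1) { ga.push_back(a[i - 1]); gb.push_back('-'); --i; }
    else             { ga.push_back('-'); gb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}

// Profile-profile global alignment for progressive MSA.
// pa, pb: 5 x L frequency matrices (rows A,C,G,T,N; columns sum to <= 1,
// remainder = gap frequency, which scores 0 against anything).
// Returns the operation path from the start: 0 diag, 1 up (consume pa),
// 2 left (consume pb). Same tie-breaking as nw_align_cpp so that aligning
// two single-sequence profiles reproduces the pairwise global alignment.
// [[Rcpp::export]]
IntegerVector profile_nw_cpp(NumericMatrix pa, NumericMatrix pb,
                             double match, double mismatch, double gap) {
  const int n = pa.ncol(), m = pb.ncol();
  // column-column expected score over residue pairs; N mismatches everything
  std::vector<double> colA_sum(n), colB_sum(m);
  for (int i = 0; i < n; ++i) {
    double s = 0; for (int r = 0; r < 5; ++r) s += pa(r, i);
    colA_sum[i] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int r = 0; r < 5; ++r) s += pb(r, j);
    colB_sum[j] = s;
  }
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> ptr((n + 1) * (m + 1));
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; ptr[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    ptr[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      // expected substitution score; pairs involving N score mismatch
      double same = 0.0;
      for (int r = 0; r < 4; ++r) same += pa(r, i - 1) * pb(r, j - 1);
      double nA = pa(4, i - 1), nB = pb(4, j - 1);
      double total = colA_sum[i - 1] * colB_sum[j - 1];
      double nonN = (colA_sum[i - 1] - nA) * (colB_sum[j - 1] - nB);
      double sameNonN = same; // N-N pairs are not "same" by construction below
      double sub = sameNonN * match +
                   (nonN - sameNonN) * mismatch +
                   (total - nonN) * mismatch;
      double d = prev[j - 1] + sub;
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      if (d >= u && d >= l)      { cur[j] = d; ptr[i * (m + 1) + j] = 0; }
      else if (u >= l)           { cur[j] = u; ptr[i * (m + 1) + j] = 1; }
      else                       { cur[j] = l; ptr[i * (m + 1) + j] = 2; }
    }
    std::swap(prev, cur);
  }
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[i * (m + 1) + j];
    ops.push_back(p);
    if (p == 0)      { --i; --j; }
    else if (p == 1) { --i; }
    else             { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Mismatch-tolerant word-match dotplot segments (plus orientation only;
// the caller handles the reverse strand by reverse-complementing b).
// A diagonal position run is reported when every k-window inside it has
// <= S mismatches; coordinates are 0-based half-open.
// [[Rcpp::export]]
DataFrame wordmatch_cpp(std::string a, std::string b, int k, int S) {
  const int n = a.size(), m = b.size();
  std::vector<int> astart, aend, bstart, bend, mismv;
  if (k > n || k > m) {
    return DataFrame::create(_["a_start"] = astart, _["a_end"] = aend,
                             _["b_start"] = bstart, _["b_end"] = bend,
                             _["mismatches"] = mismv);
  }
  for (int d = -(m - k); d <= n - k; ++d) {
    int i0 = d > 0 ? d : 0;
    int j0 = d > 0 ? 0 : -d;
    int len = std::min(n - i0, m - j0);
    if (len < k) continue;
    // mm[t] = 1 if a[i0+t] != b[j0+t] (N never matches)
    std::vector<int> mm(len);
    for (int t = 0; t < len; ++t) {
      char x = a[i0 + t], y = b[j0 + t];
      mm[t] = (x == y && x != 'N') ? 0 : 1;
    }
    int ws = 0;
    for (int t = 0; t < k; ++t) ws += mm[t];
    int runStart = -1;
    int nwin = len - k + 1;
    for (int t = 0; t < nwin; ++t) {
      if (t > 0) ws += mm[t + k - 1] - mm[t - 1];
      bool good = (ws <= S);
      if (good && runStart < 0) runStart = t;
      if ((!good || t == nwin - 1) && runStart >= 0) {
        int runEnd = good ? t : t - 1; // last good window start
        int s0 = runStart, s1 = runEnd + k; // [s0, s1) span on diagonal
        int misc = 0;
        for (int t2 = s0; t2 < s1; ++t2) misc += mm[t2];
        astart.push_back(i0 + s0); aend.push_back(i0 + s1);
        bstart.push_back(j0 + s0); bend.push_back(j0 + s1);
        mismv.push_back(misc);
        runStart = -1;
      }
    }
  }
  return DataFrame::create(_["a_start"] = astart, _["a_end"] = aend,
                           _["b_start"] = bstart, _["b_end"] = bend,
                           _["mismatches"] = mismv);
}

// Windowed dotplot: reports 0-based (i, j) window starts whose w-length
// gapless comparison scores >= threshold under match/mismatch scoring.
// [[Rcpp::export]]
List windowed_dotplot_cpp(std::string a, std::string b, int w,
                          double match, double mismatch, double threshold) {
  const int n = a.size(), m = b.size();
  std::vector<int> iv, jv;
  if (w <= n && w <= m) {
    for (int d = -(m - w); d <= n - w; ++d) {
      int i0 = d > 0 ? d : 0;
      int j0 = d > 0 ? 0 : -d;
      int len = std::min(n - i0, m - j0);
      if (len < w) continue;
      double ws = 0.0;
      std::vector<double> sc(len);
      for (int t = 0; t < len; ++t) {
        char x = a[i0 + t], y = b[j0 + t];
        sc[t] = (x == y && x != 'N') ? match : mismatch;
      }
      for (int t = 0; t < w; ++t) ws += sc[t];
      int nwin = len - w + 1;
      for (int t = 0; t < nwin; ++t) {
        if (t > 0) ws += sc[t + w - 1] - sc[t - 1];
        if (ws >= threshold) { iv.push_back(i0 + t); jv.push_back(j0 + t); }
      }
    }
  }
  return List::create(_["i"] = iv, _["j"] = jv);
}
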