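#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap costs follow the BLAST convention: a gap of
// length L costs gap_open + L * gap_extend, i.e. the first gapped residue
// costs gap_open + gap_extend.

static const int NEG = -100000000;

static void encode(const std::string &s, const IntegerVector &charmap,
                   std::vector<int> &out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    out[i] = charmap[(unsigned char)s[i]];
}

static int sw_score_scalar(const std::vector<int> &srow, int m, int nl,
                           const std::vector<int> &b, int gi, int gap_ext) {
  const int n = (int)b.size();
  std::vector<int> H(n + 1, 0), V(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int *sr = &srow[(size_t)(i - 1) * nl];
    int diag = 0;  // H[i-1][j-1]
    int Hz = NEG;  // gap in query, current row
    for (int j = 1; j <= n; ++j) {
      V[j] = std::max(H[j] - gi, V[j] - gap_ext);
      Hz = std::max(H[j - 1] - gi, Hz - gap_ext);
      int h = diag + sr[b[j - 1]];
      if (V[j] > h) h = V[j];
      if (Hz > h) h = Hz;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

#ifdef __SSE2__
#include <emmintrin.h>

// Striped Smith-Waterman (Farrar 2007), 8 lanes of 16-bit scores. The
// query profile is built once per query and reused across subjects. The
// lazy-F loop also refreshes E so scores are exact for any scoring scheme.
static int sw_score_striped16(const std::vector<__m128i> &prof, int segLen,
                              const std::vector<int> &b, int gi, int ge) {
  const int n = (int)b.size();
  std::vector<__m128i> Hs(segLen), Hl(segLen), Es(segLen);
  const __m128i vZero = _mm_setzero_si128();
  const __m128i vNeg = _mm_set1_epi16(-32000);
  const __m128i vGi = _mm_set1_epi16((short)gi);
  const __m128i vGe = _mm_set1_epi16((short)ge);
  for (int k = 0; k < segLen; ++k) { Hs[k] = vZero; Es[k] = vNeg; }
  __m128i vBest = vZero;
  for (int j = 0; j < n; ++j) {
    const __m128i *vP = &prof[(size_t)b[j] * segLen];
    __m128i vF = vNeg;
    __m128i vH = _mm_slli_si128(Hs[segLen - 1], 2);
    std::swap(Hs, Hl);
    for (int k = 0; k < segLen; ++k) {
      vH = _mm_adds_epi16(vH, vP[k]);
      vH = _mm_max_epi16(vH, Es[k]);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      vBest = _mm_max_epi16(vBest, vH);
      Hs[k] = vH;
      const __m128i vHg = _mm_subs_epi16(vH, vGi);
      Es[k] = _mm_max_epi16(_mm_subs_epi16(Es[k], vGe), vHg);
      vF = _mm_max_epi16(_mm_subs_epi16(vF, vGe), vHg);
      vH = Hl[k];
    }
    // lazy F: keep propagating vertical gaps across stripe boundaries
    vF = _mm_slli_si128(vF, 2);
    vF = _mm_insert_epi16(vF, -32000, 0);
    int k = 0, guard = 0;
    const int guard_max = segLen * 10;
    while (guard++ < guard_max) {
      const __m128i vHk = Hs[k];
      if (_mm_movemask_epi8(_mm_cmpgt_epi16(vF, vHk)) != 0) {
        const __m128i vT = _mm_max_epi16(vHk, vF);
        Hs[k] = vT;
        vBest = _mm_max_epi16(vBest, vT);
        Es[k] = _mm_max_epi16(Es[k], _mm_subs_epi16(vT, vGi));
      }
      const __m128i vHo = _mm_subs_epi16(Hs[k], vGi);
      vF = _mm_subs_epi16(vF, vGe);
      if (_mm_movemask_epi8(_mm_cmpgt_epi16(vF, vHo)) == 0) break;
      if (++k == segLen) {
        k = 0;
        vF = _mm_slli_si128(vF, 2);
        vF = _mm_insert_epi16(vF, -32000, 0);
      }
    }
  }
  short lanes[8];
  _mm_storeu_si128((__m128i *)lanes, vBest);
  int best = 0;
  for (int l = 0; l < 8; ++l)
    if (lanes[l] > best) best = lanes[l];
  return best;
}
#endif

// Best local alignment score of `query` against each subject (score only).
// [[Rcpp::export]]
IntegerVector sw_score_batch_cpp(std::string query,
                                 std::vector<std::string> subjects,
                                 IntegerVector charmap, IntegerMatrix submat,
                                 int gap_open, int gap_ext) {
  std::vector<int> q;
  encode(query, charmap, q);
  const int m = (int)q.size();
  const int nl = submat.nrow();
  const int gi = gap_open + gap_ext;
  const int ns = (int)subjects.size();
  IntegerVector out(ns);
  std::vector<int> b;
#ifdef __SSE2__
  const int segLen = (m + 7) / 8;
  std::vector<__m128i> prof((size_t)nl * segLen);
  for (int a = 0; a < nl; ++a) {
    for (int k = 0; k < segLen; ++k) {
      short lane[8];
      for (int l = 0; l < 8; ++l) {
        const int pos = l * segLen + k;
        lane[l] = (pos < m) ? (short)submat(q[pos], a) : (short)-32000;
      }
      prof[(size_t)a * segLen + k] = _mm_loadu_si128((__m128i *)lane);
    }
  }
  for (int s = 0; s < ns; ++s) {
    encode(subjects[s], charmap, b);
    out[s] = sw_score_striped16(prof, segLen, b, gi, gap_ext);
  }
#else
  std::vector<int> srow((size_t)m * nl);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < nl; ++a)
      srow[(size_t)i * nl + a] = submat(q[i], a);
  for (int s = 0; s < ns; ++s) {
    encode(subjects[s], charmap, b);
    out[s] = sw_score_scalar(srow, m, nl, b, gi, gap_ext);
  }
#endif
  return out;
}

// Scalar reference scorer (same semantics as the batch scorer; used for
// cross-checking the vectorized kernel).
// [[Rcpp::export]]
IntegerVector sw_score_batch_scalar_cpp(std::string query,
                                        std::vector<std::string> subjects,
                                        IntegerVector charmap,
                                        IntegerMatrix submat, int gap_open,
                                        int gap_ext) {
  std::vector<int> q;
  encode(query, charmap, q);
  const int m = (int)q.size();
  const int nl = submat.nrow();
  std::vector<int> srow((size_t)m * nl);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < nl; ++a)
      srow[(size_t)i * nl + a] = submat(q[i], a);
  const int ns = (int)subjects.size();
  IntegerVector out(ns);
  std::vector<int> b;
  for (int s = 0; s < ns; ++s) {
    encode(subjects[s], charmap, b);
    out[s] = sw_score_scalar(srow, m, nl, b, gap_open + gap_ext, gap_ext);
  }
  return out;
}

// Full Smith-Waterman with traceback. Ties during traceback are broken
// diagonal > up (gap in b) > left (gap in a); the best cell is the first
// maximal cell in row-major order, so the result is deterministic.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerVector charmap,
                  IntegerMatrix submat, int gap_open, int gap_ext) {
  std::vector<int> x, y;
  encode(a, charmap, x);
  encode(b, charmap, y);
  const int m = (int)x.size(), n = (int)y.size();
  const int gi = gap_open + gap_ext;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> V((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> Hz((size_t)(m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t c = idx(i, j);
      V[c] = std::max(H[idx(i - 1, j)] - gi, V[idx(i - 1, j)] - gap_ext);
      Hz[c] = std::max(H[idx(i, j - 1)] - gi, Hz[idx(i, j - 1)] - gap_ext);
      int h = H[idx(i - 1, j - 1)] + submat(x[i - 1], y[j - 1]);
      if (V[c] > h) h = V[c];
      if (Hz[c] > h) h = Hz[c];
      if (h < 0) h = 0;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string aln_a, aln_b;
  int i = bi, j = bj, n_ident = 0;
  int state = 0;  // 0 = H, 1 = V (gap in b), 2 = Hz (gap in a)
  while (i > 0 && j > 0) {
    const size_t c = idx(i, j);
    if (state == 0) {
      if (H[c] == 0) break;
      const int sc = submat(x[i - 1], y[j - 1]);
      if (H[c] == H[idx(i - 1, j - 1)] + sc) {
        aln_a.push_back(a[i - 1]);
        aln_b.push_back(b[j - 1]);
        if (x[i - 1] == y[j - 1]) ++n_ident;
        --i; --j;
      } else if (H[c] == V[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      aln_a.push_back(a[i - 1]);
      aln_b.push_back('-');
      // prefer closing the gap on ties
      if (V[c] == H[idx(i - 1, j)] - gi) state = 0;
      --i;
    } else {
      aln_a.push_back('-');
      aln_b.push_back(b[j - 1]);
      if (Hz[c] == H[idx(i, j - 1)] - gi) state = 0;
      --j;
    }
  }
  std::reverse(aln_a.begin(), aln_a.end());
  std::reverse(aln_b.begin(), aln_b.end());
  return List::create(
      _["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
      _["b_start"] = j + 1, _["b_end"] = bj, _["n_ident"] = n_ident,
      _["aln_len"] = (int)aln_a.size(), _["aln_a"] = aln_a, _["aln_b"] = aln_b);
}

// Profile-profile global alignment with affine gaps and free terminal gaps.
// A and B are integer matrices (rows = sequences, cols = alignment columns),
// entries in 0..(nl-1) or -1 for a gap. Column score is the expected
// substitution score between residues drawn from the two column profiles
// (gap rows contribute zero). Returns, for each output column, the source
// column in A and in B (0 = gap).
// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix submat,
                       double gap_open, double gap_ext) {
  const int nl = submat.nrow();
  const int la = A.ncol(), lb = B.ncol();
  const int na = A.nrow(), nb = B.nrow();
  // profiles: nl x len, residue frequencies (denominator = nrow)
  std::vector<double> fa((size_t)nl * la, 0.0), fb((size_t)nl * lb, 0.0);
  for (int j = 0; j < la; ++j)
    for (int i = 0; i < na; ++i)
      if (A(i, j) >= 0) fa[(size_t)j * nl + A(i, j)] += 1.0 / na;
  for (int j = 0; j < lb; ++j)
    for (int i = 0; i < nb; ++i)
      if (B(i, j) >= 0) fb[(size_t)j * nl + B(i, j)] += 1.0 / nb;
  // precompute S * fa per column of A
  std::vector<double> sfa((size_t)nl * la, 0.0);
  for (int j = 0; j < la; ++j)
    for (int a = 0; a < nl; ++a) {
      double acc = 0.0;
      for (int b2 = 0; b2 < nl; ++b2) acc += submat(a, b2) * fa[(size_t)j * nl + b2];
      sfa[(size_t)j * nl + a] = acc;
    }
  auto colscore = [&](int i, int j) {  // i: column of A (1-based), j: of B
    const double *s = &sfa[(size_t)(i - 1) * nl];
    const double *f = &fb[(size_t)(j - 1) * nl];
    double acc = 0.0;
    for (int a = 0; a < nl; ++a) acc += s[a] * f[a];
    return acc;
  };
  const double NEGD = -1e18;
  const double gi = gap_open + gap_ext;
  std::vector<double> M((size_t)(la + 1) * (lb + 1), NEGD);
  std::vector<double> GA((size_t)(la + 1) * (lb + 1), NEGD);  // gap in B (consume A)
  std::vector<double> GB((size_t)(la + 1) * (lb + 1), NEGD);  // gap in A (consume B)
  auto idx = [lb](int i, int j) { return (size_t)i * (lb + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) GA[idx(i, 0)] = 0.0;  // free leading gaps
  for (int j = 1; j <= lb; ++j) GB[idx(0, j)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const size_t c = idx(i, j);
      const size_t up = idx(i - 1, j), lf = idx(i, j - 1), dg = idx(i - 1, j - 1);
      GA[c] = std::max(std::max(M[up] - gi, GA[up] - gap_ext), GB[up] - gi);
      GB[c] = std::max(std::max(M[lf] - gi, GB[lf] - gap_ext), GA[lf] - gi);
      double best = std::max(std::max(M[dg], GA[dg]), GB[dg]) + colscore(i, j);
      M[c] = best;
    }
  }
  // free trailing gaps: end anywhere on last row/col, deterministic preference
  double best = NEGD;
  int ei = la, ej = lb, estate = 0;
  for (int st = 0; st < 3; ++st) {
    // consider (la, lb) directly
    double v = (st == 0 ? M[idx(la, lb)] : (st == 1 ? GA[idx(la, lb)] : GB[idx(la, lb)]));
    if (v > best) { best = v; ei = la; ej = lb; estate = st; }
  }
  for (int i = la - 1; i >= 0; --i) {
    double v = std::max(std::max(M[idx(i, lb)], GA[idx(i, lb)]), GB[idx(i, lb)]);
    if (v > best + 1e-9) {
      best = v; ei = i; ej = lb;
      estate = (M[idx(i, lb)] >= v - 1e-12) ? 0 : ((GA[idx(i, lb)] >= v - 1e-12) ? 1 : 2);
    }
  }
  for (int j = lb - 1; j >= 0; --j) {
    double v = std::max(std::max(M[idx(la, j)], GA[idx(la, j)]), GB[idx(la, j)]);
    if (v > best + 1e-9) {
      best = v; ei = la; ej = j;
      estate = (M[idx(la, j)] >= v - 1e-12) ? 0 : ((GA[idx(la, j)] >= v - 1e-12) ? 1 : 2);
    }
  }
  std::vector<int> outa, outb;
  // trailing free gaps
  for (int j = lb; j > ej; --j) { outa.push_back(0); outb.push_back(j); }
  for (int i = la; i > ei; --i) { outa.push_back(i); outb.push_back(0); }
  int i = ei, j = ej, state = estate;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    const size_t c = idx(i, j);
    if (i == 0) { outa.push_back(0); outb.push_back(j); --j; continue; }
    if (j == 0) { outa.push_back(i); outb.push_back(0); --i; continue; }
    if (state == 0) {
      const size_t dg = idx(i - 1, j - 1);
      const double cs = colscore(i, j);
      outa.push_back(i); outb.push_back(j);
      if (std::abs(M[c] - (M[dg] + cs)) < eps) state = 0;
      else if (std::abs(M[c] - (GA[dg] + cs)) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const size_t up = idx(i - 1, j);
      outa.push_back(i); outb.push_back(0);
      if (std::abs(GA[c] - (M[up] - gi)) < eps) state = 0;
      else if (std::abs(GA[c] - (GA[up] - gap_ext)) < eps) state = 1;
      else state = 2;
      --i;
      if (i == 0) state = 2;  // remaining B columns are leading gaps
    } else {
      const size_t lf = idx(i, j - 1);
      outa.push_back(0); outb.push_back(j);
      if (std::abs(GB[c] - (M[lf] - gi)) < eps) state = 0;
      else if (std::abs(GB[c] - (GB[lf] - gap_ext)) < eps) state = 2;
      else state = 1;
      --j;
      if (j == 0) state = 1;
    }
  }
  std::reverse(outa.begin(), outa.end());
  std::reverse(outb.begin(), outb.end());
  return List::create(_["score"] = best, _["map_a"] = wrap(outa),
                      _["map_b"] = wrap(outb));
}
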