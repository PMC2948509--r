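// Dynamic-programming kernels: affine-gap global and local pairwise alignment,
// per-pair transition/transversion counting, and glocal profile Viterbi with
// shuffle-based score calibration.
//
// Gap convention throughout: a gap run of length L costs gap_open for its first
// gap character and gap_extend for each additional one (both negative).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

static const double NEG_INF = -1e30;

static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline double subst_score(char a, char b, double match, double mismatch) {
  int ia = base_idx(a), ib = base_idx(b);
  if (ia < 0 || ib < 0) return mismatch; // N against anything scores as mismatch
  return (ia == ib) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) affine alignment with traceback.
// Tie order on equal score: match/mismatch, then gap-in-a, then gap-in-b.
// ---------------------------------------------------------------------------

struct NWResult {
  std::string a_aln, b_aln;
  double score;
  int transitions, transversions, comparable;
};

static inline bool is_transition(int ia, int ib) {
  // A<->G (0,2) and C<->T (1,3)
  return (ia + ib == 2 && ia != ib) || (ia + ib == 4 && ia != ib);
}

static NWResult nw_align_core(const std::string& a, const std::string& b,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              bool traceback) {
  const int n = a.size(), m = b.size();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // X: gap character in b (consumes a); Y: gap character in a (consumes b)
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[j] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + subst_score(a[i - 1], b[j - 1], match, mismatch);
      double xo = M[u] + gap_open, xe = X[u] + gap_extend, xy = Y[u] + gap_open;
      X[c] = std::max(std::max(xo, xe), xy);
      double yo = M[l] + gap_open, ye = Y[l] + gap_extend, yx = X[l] + gap_open;
      Y[c] = std::max(std::max(yo, ye), yx);
    }
  }

  NWResult res;
  const size_t e = n * W + m;
  res.score = std::max(std::max(M[e], Y[e]), X[e]);
  res.transitions = res.transversions = res.comparable = 0;
  if (!traceback) return res;

  // state 0 = M, 1 = Y (gap in a), 2 = X (gap in b); preference in that order
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  int state;
  {
    const size_t c = i * W + j;
    if (M[c] >= Y[c] && M[c] >= X[c]) state = 0;
    else if (Y[c] >= X[c]) state = 1;
    else state = 2;
  }
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      int ia = base_idx(a[i - 1]), ib = base_idx(b[j - 1]);
      if (ia >= 0 && ib >= 0) {
        ++res.comparable;
        if (ia != ib) {
          if (is_transition(ia, ib)) ++res.transitions; else ++res.transversions;
        }
      }
      const size_t d = (i - 1) * W + (j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[d] >= Y[d] && M[d] >= X[d]) state = 0;
      else if (Y[d] >= X[d]) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in a, consume b[j]
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const size_t l = i * W + (j - 1);
      double yo = M[l] + gap_open, ye = Y[l] + gap_extend, yx = X[l] + gap_open;
      double mx = std::max(std::max(yo, ye), yx);
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) { state = 2; continue; } // only leading gaps in b remain? handled below
      if (yo == mx) state = 0; else if (ye == mx) state = 1; else state = 2;
    } else { // gap in b, consume a[i]
      ra.push_back('-'); // placeholder, fixed below (gap goes in b)
      ra.back() = a[i - 1]; rb.push_back('-');
      const size_t u = (i - 1) * W + j;
      double xo = M[u] + gap_open, xe = X[u] + gap_extend, xy = Y[u] + gap_open;
      double mx = std::max(std::max(xo, xe), xy);
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 1; continue; }
      if (xo == mx) state = 0; else if (xy == mx) state = 1; else state = 2;
    }
    if (i == 0 && j > 0) state = 1;
    else if (j == 0 && i > 0) state = 2;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.a_aln = ra; res.b_aln = rb;
  return res;
}

// [[Rcpp::export(name = ".c_nw_align")]]
List c_nw_align(std::string a, std::string b, double match, double mismatch,
                double gap_open, double gap_extend) {
  NWResult r = nw_align_core(a, b, match, mismatch, gap_open, gap_extend, true);
  return List::create(_["a"] = r.a_aln, _["b"] = r.b_aln, _["score"] = r.score);
}

// [[Rcpp::export(name = ".c_nw_score")]]
double c_nw_score(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  return nw_align_core(a, b, match, mismatch, gap_open, gap_extend, false).score;
}

// All-pairs transition/transversion/comparable counts after global alignment.
// [[Rcpp::export(name = ".c_k2p_counts")]]
List c_k2p_counts(CharacterVector seqs, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = seqs.size();
  IntegerMatrix ts(n, n), tv(n, n), nc(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      NWResult r = nw_align_core(ss[i], ss[j], match, mismatch, gap_open,
                                 gap_extend, true);
      ts(i, j) = ts(j, i) = r.transitions;
      tv(i, j) = tv(j, i) = r.transversions;
      nc(i, j) = nc(j, i) = r.comparable;
    }
    // diagonal: self-comparison, all columns comparable-identical
    int self = 0;
    for (char c : ss[i]) if (base_idx(c) >= 0) ++self;
    nc(i, i) = self;
  }
  return List::create(_["transitions"] = ts, _["transversions"] = tv,
                      _["comparable"] = nc);
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) affine alignment.
// ---------------------------------------------------------------------------

// Full-matrix local alignment; returns best score, and optionally match count
// and alignment length of the best local alignment via traceback.
static void sw_full(const std::string& a, const std::string& b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool traceback,
                    double* out_score, int* out_matches, int* out_cols) {
  const int n = a.size(), m = b.size();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double diag = std::max(std::max(M[d], X[d]), std::max(Y[d], 0.0));
      M[c] = diag + subst_score(a[i - 1], b[j - 1], match, mismatch);
      if (M[c] < 0.0) M[c] = 0.0;
      X[c] = std::max(std::max(M[u] + gap_open, X[u] + gap_extend),
                      Y[u] + gap_open);
      Y[c] = std::max(std::max(M[l] + gap_open, Y[l] + gap_extend),
                      X[l] + gap_open);
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  *out_score = best;
  if (!traceback) return;
  int matches = 0, cols = 0;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    const size_t c = i * W + j;
    if (state == 0) {
      if (M[c] <= 0.0) break;
      ++cols;
      if (base_idx(a[i - 1]) >= 0 && base_idx(a[i - 1]) == base_idx(b[j - 1]))
        ++matches;
      const size_t d = (i - 1) * W + (j - 1);
      double prev = M[c] - subst_score(a[i - 1], b[j - 1], match, mismatch);
      --i; --j;
      if (prev <= 0.0 || (i == 0 || j == 0)) break;
      if (std::abs(M[d] - prev) < 1e-9) state = 0;
      else if (std::abs(X[d] - prev) < 1e-9) state = 2;
      else if (std::abs(Y[d] - prev) < 1e-9) state = 1;
      else break; // started from 0
    } else if (state == 2) { // gap in b, consume a
      ++cols;
      const size_t u = (i - 1) * W + j;
      double cur = X[i * W + j];
      --i;
      if (std::abs(M[u] + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X[u] + gap_extend - cur) < 1e-9) state = 2;
      else state = 1;
    } else { // gap in a, consume b
      ++cols;
      const size_t l = i * W + (j - 1);
      double cur = Y[i * W + j];
      --j;
      if (std::abs(M[l] + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y[l] + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    }
  }
  *out_matches = matches;
  *out_cols = cols;
}

// [[Rcpp::export(name = ".c_sw_scores")]]
NumericVector c_sw_scores(std::string query, CharacterVector subjects,
                          double match, double mismatch, double gap_open,
                          double gap_extend) {
  const int n = subjects.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(subjects[k]);
    double sc; int mm, cc;
    sw_full(query, s, match, mismatch, gap_open, gap_extend, false, &sc, &mm, &cc);
    out[k] = sc;
  }
  return out;
}

// [[Rcpp::export(name = ".c_sw_stats")]]
List c_sw_stats(std::string query, std::string subject, double match,
                double mismatch, double gap_open, double gap_extend) {
  double sc; int mm = 0, cc = 0;
  sw_full(query, subject, match, mismatch, gap_open, gap_extend, true, &sc, &mm, &cc);
  return List::create(_["score"] = sc, _["matches"] = mm, _["columns"] = cc);
}

// ---------------------------------------------------------------------------
// Glocal profile alignment (whole model, local target), Viterbi in log-odds.
// ---------------------------------------------------------------------------

static void profile_viterbi(const NumericMatrix& lo, // 4 x L log-odds (bits)
                            const NumericVector& gap_open,   // length L
                            const NumericVector& gap_extend, // length L
                            const std::string& seq,
                            double* out_score, int* out_start, int* out_end) {
  const int L = lo.ncol(), n = seq.size();
  const size_t W = n + 1;
  std::vector<double> M(W, NEG_INF), I(W, NEG_INF), D(W, NEG_INF);
  std::vector<double> Mn(W), In(W), Dn(W);
  std::vector<int> sM(W, 0), sI(W, 0), sD(W, 0), sMn(W), sIn(W), sDn(W);

  // j = 1
  for (int i = 0; i <= n; ++i) {
    if (i >= 1) {
      int b = base_idx(seq[i - 1]);
      M[i] = (b >= 0) ? lo(b, 0) : 0.0;
      sM[i] = i - 1;
    }
    D[i] = gap_open[0];
    sD[i] = i;
  }
  // insertions after column 1
  for (int i = 1; i <= n; ++i) {
    double io = M[i - 1] + gap_open[0], ie = I[i - 1] + gap_extend[0];
    if (io >= ie) { I[i] = io; sI[i] = sM[i - 1]; }
    else { I[i] = ie; sI[i] = sI[i - 1]; }
  }

  for (int j = 2; j <= L; ++j) {
    const double go = gap_open[j - 1], ge = gap_extend[j - 1];
    Mn[0] = NEG_INF; In[0] = NEG_INF;
    // deletions consume no target
    {
      double d1 = M[0] + go, d2 = D[0] + ge, d3 = I[0] + go;
      Dn[0] = std::max(std::max(d1, d2), d3);
      sDn[0] = (d1 >= d2 && d1 >= d3) ? sM[0] : ((d2 >= d3) ? sD[0] : sI[0]);
    }
    for (int i = 1; i <= n; ++i) {
      // match
      double pm = M[i - 1], pi = I[i - 1], pd = D[i - 1];
      double bestp = pm; int bests = sM[i - 1];
      if (pi > bestp) { bestp = pi; bests = sI[i - 1]; }
      else if (pi == bestp && sI[i - 1] < bests) bests = sI[i - 1];
      if (pd > bestp) { bestp = pd; bests = sD[i - 1]; }
      else if (pd == bestp && sD[i - 1] < bests) bests = sD[i - 1];
      int b = base_idx(seq[i - 1]);
      double em = (b >= 0) ? lo(b, j - 1) : 0.0;
      Mn[i] = bestp + em; sMn[i] = bests;
      // delete model column j
      double d1 = M[i] + go, d2 = D[i] + ge, d3 = I[i] + go;
      Dn[i] = std::max(std::max(d1, d2), d3);
      sDn[i] = (d1 >= d2 && d1 >= d3) ? sM[i] : ((d2 >= d3) ? sD[i] : sI[i]);
      // insertion after column j (uses current j arrays)
      double io = Mn[i - 1] + go, ie = In[i - 1] + ge;
      if (io >= ie) { In[i] = io; sIn[i] = sMn[i - 1]; }
      else { In[i] = ie; sIn[i] = sIn[i - 1]; }
    }
    std::swap(M, Mn); std::swap(I, In); std::swap(D, Dn);
    std::swap(sM, sMn); std::swap(sI, sIn); std::swap(sD, sDn);
  }

  double best = NEG_INF; int bs = 0, be = 0;
  for (int i = 0; i <= n; ++i) {
    if (M[i] > best) { best = M[i]; bs = sM[i]; be = i; }
    if (D[i] > best) { best = D[i]; bs = sD[i]; be = i; }
  }
  *out_score = best; *out_start = bs; *out_end = be;
}

// [[Rcpp::export(name = ".c_profile_scan")]]
List c_profile_scan(NumericMatrix log_odds, NumericVector gap_open,
                    NumericVector gap_extend, std::string seq) {
  double sc; int s, e;
  profile_viterbi(log_odds, gap_open, gap_extend, seq, &sc, &s, &e);
  return List::create(_["score"] = sc, _["start"] = s, _["end"] = e);
}

// Best scores of the model against n_shuffle seeded shuffles of the target.
// [[Rcpp::export(name = ".c_profile_calibrate")]]
NumericVector c_profile_calibrate(NumericMatrix log_odds, NumericVector gap_open,
                                  NumericVector gap_extend, std::string seq,
                                  int n_shuffle, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::string s = seq;
  NumericVector out(n_shuffle);
  for (int k = 0; k < n_shuffle; ++k) {
    for (int i = (int)s.size() - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      int j = u(rng);
      std::swap(s[i], s[j]);
    }
    double sc; int a, b;
    profile_viterbi(log_odds, gap_open, gap_extend, s, &sc, &a, &b);
    out[k] = sc;
  }
  return out;
}
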