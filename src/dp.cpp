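// Dynamic-programming core: local-in-model / local-in-target Viterbi and
// forward scoring of a peptide against a profile-HMM scoring model, with an
// optional diagonal band.  Scores are in bits (log2).
//
// Transition column order (source-state indexed):
//   0 M->M, 1 M->I, 2 M->D, 3 I->M, 4 I->I, 5 D->M, 6 D->D
// Target residues are 0..19 integer codes; -1 encodes 'X' (unknown), which
// emits at a fixed mild penalty rather than -Inf.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double NEG = -1e30;      // -Inf sentinel, safe under addition
static const double X_EMIT = -2.0;    // emission score (bits) for 'X'

// log2(2^a + 2^b), guarded for the sentinel
static inline double lse2(double a, double b) {
  if (a < b) { double t = a; a = b; b = t; }
  if (b <= NEG / 2) return a;
  double d = b - a;                    // <= 0
  if (d < -60.0) return a;
  return a + std::log1p(std::pow(2.0, d)) / M_LN2;
}

static inline double emit_at(const NumericMatrix& em, int i, int code) {
  return (code < 0) ? X_EMIT : em(i, code);
}

// Shared DP. If fwd is true computes the forward (all-parse) score, else
// Viterbi.  Band: cells (i, j) with |(i - j) - diag0| > d are never written;
// pass d >= L + n for an unbanded computation.  Alignments enter and exit at
// match states (uni-hit local mode).
static double dp_run(const NumericMatrix& emitM, const NumericMatrix& emitI,
                     const NumericMatrix& tr, const std::vector<int>& tgt,
                     int d, int diag0, bool fwd,
                     std::vector<signed char>* bpM, std::vector<signed char>* bpI,
                     std::vector<signed char>* bpD, int* best_i, int* best_j) {
  const int L = emitM.nrow();
  const int n = (int) tgt.size();
  const size_t NC = (size_t)(L + 1) * (size_t)(n + 1);
  std::vector<double> M(NC, NEG), I(NC, NEG), D(NC, NEG);
  auto idx = [n](int i, int j) { return (size_t) i * (size_t)(n + 1) + j; };

  double best = NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    int jlo = i - diag0 - d, jhi = i - diag0 + d;
    if (jlo < 1) jlo = 1;
    if (jhi > n) jhi = n;
    for (int j = jlo; j <= jhi; ++j) {
      const int a = tgt[j - 1];
      // match: from M/I/D at (i-1, j-1) or fresh local start
      double m;
      signed char whoM = 0;          // 0 start, 1 M, 2 I, 3 D
      if (fwd) {
        double acc = 0.0;            // 2^0 for the local start
        if (i > 1) {
          acc = lse2(acc, M[idx(i - 1, j - 1)] + tr(i - 2, 0));
          acc = lse2(acc, I[idx(i - 1, j - 1)] + tr(i - 2, 3));
          acc = lse2(acc, D[idx(i - 1, j - 1)] + tr(i - 2, 5));
        }
        m = emit_at(emitM, i - 1, a) + acc;
      } else {
        double bestp = 0.0;          // local start
        if (i > 1) {
          double c = M[idx(i - 1, j - 1)] + tr(i - 2, 0);
          if (c > bestp) { bestp = c; whoM = 1; }
          c = I[idx(i - 1, j - 1)] + tr(i - 2, 3);
          if (c > bestp) { bestp = c; whoM = 2; }
          c = D[idx(i - 1, j - 1)] + tr(i - 2, 5);
          if (c > bestp) { bestp = c; whoM = 3; }
        }
        m = emit_at(emitM, i - 1, a) + bestp;
      }
      M[idx(i, j)] = m;
      if (bpM) (*bpM)[idx(i, j)] = whoM;

      // delete: from M/D at (i-1, j); interior only (i >= 2)
      if (i > 1) {
        double dm = M[idx(i - 1, j)] + tr(i - 2, 2);
        double dd = D[idx(i - 1, j)] + tr(i - 2, 6);
        if (fwd) {
          D[idx(i, j)] = lse2(dm, dd);
        } else {
          if (dm >= dd) { D[idx(i, j)] = dm; if (bpD) (*bpD)[idx(i, j)] = 1; }
          else          { D[idx(i, j)] = dd; if (bpD) (*bpD)[idx(i, j)] = 3; }
        }
      }

      // insert: from M/I at (i, j-1)
      {
        double im = M[idx(i, j - 1)] + tr(i - 1, 1);
        double ii = I[idx(i, j - 1)] + tr(i - 1, 4);
        double e = emit_at(emitI, i - 1, a);
        if (fwd) {
          double acc = lse2(im, ii);
          I[idx(i, j)] = (acc <= NEG / 2) ? NEG : e + acc;
        } else {
          double bestp; signed char who;
          if (im >= ii) { bestp = im; who = 1; } else { bestp = ii; who = 2; }
          I[idx(i, j)] = (bestp <= NEG / 2) ? NEG : e + bestp;
          if (bpI) (*bpI)[idx(i, j)] = who;
        }
      }

      // terminal: exit at a match state
      if (fwd) {
        best = lse2(best, m);
      } else if (m > best) {
        best = m; bi = i; bj = j;
      }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

static std::vector<int> as_codes(const IntegerVector& v) {
  std::vector<int> t(v.size());
  for (int i = 0; i < v.size(); ++i) t[i] = v[i];
  return t;
}

// [[Rcpp::export]]
List cpp_local_viterbi(NumericMatrix emitM, NumericMatrix emitI,
                       NumericMatrix tr, IntegerVector target,
                       int d, int diag0, bool traceback) {
  std::vector<int> tgt = as_codes(target);
  const int L = emitM.nrow(), n = (int) tgt.size();
  const size_t NC = (size_t)(L + 1) * (size_t)(n + 1);
  int bi = 0, bj = 0;
  double sc;
  if (!traceback) {
    sc = dp_run(emitM, emitI, tr, tgt, d, diag0, false,
                nullptr, nullptr, nullptr, &bi, &bj);
    return List::create(_["score"] = sc, _["i_end"] = bi, _["j_end"] = bj);
  }
  std::vector<signed char> bpM(NC, 0), bpI(NC, 0), bpD(NC, 0);
  sc = dp_run(emitM, emitI, tr, tgt, d, diag0, false, &bpM, &bpI, &bpD, &bi, &bj);
  auto idx = [n](int i, int j) { return (size_t) i * (size_t)(n + 1) + j; };
  std::vector<char> st;
  std::vector<int> si, sj;
  if (sc > NEG / 2 && bi > 0) {
    int i = bi, j = bj; char s = 'M';
    while (true) {
      st.push_back(s); si.push_back(i); sj.push_back(j);
      if (s == 'M') {
        signed char w = bpM[idx(i, j)];
        if (w == 0) break;
        s = (w == 1) ? 'M' : (w == 2 ? 'I' : 'D');
        --i; --j;
      } else if (s == 'I') {
        s = (bpI[idx(i, j)] == 1) ? 'M' : 'I';
        --j;
      } else {
        s = (bpD[idx(i, j)] == 1) ? 'M' : 'D';
        --i;
      }
    }
    std::reverse(st.begin(), st.end());
    std::reverse(si.begin(), si.end());
    std::reverse(sj.begin(), sj.end());
  }
  CharacterVector states(st.size());
  for (size_t q = 0; q < st.size(); ++q) states[q] = std::string(1, st[q]);
  return List::create(_["score"] = sc, _["i_end"] = bi, _["j_end"] = bj,
                      _["state"] = states, _["i"] = wrap(si), _["j"] = wrap(sj));
}

// [[Rcpp::export]]
double cpp_local_forward(NumericMatrix emitM, NumericMatrix emitI,
                         NumericMatrix tr, IntegerVector target,
                         int d, int diag0) {
  std::vector<int> tgt = as_codes(target);
  return dp_run(emitM, emitI, tr, tgt, d, diag0, true,
                nullptr, nullptr, nullptr, nullptr, nullptr);
}

// Batch scorer for null-model calibration: one score per target sequence.
// [[Rcpp::export]]
NumericVector cpp_score_batch(NumericMatrix emitM, NumericMatrix emitI,
                              NumericMatrix tr, List targets, bool forward) {
  const int N = targets.size();
  NumericVector out(N);
  const int L = emitM.nrow();
  for (int q = 0; q < N; ++q) {
    std::vector<int> tgt = as_codes(targets[q]);
    int d = L + (int) tgt.size() + 1;
    out[q] = dp_run(emitM, emitI, tr, tgt, d, 0, forward,
                    nullptr, nullptr, nullptr, nullptr, nullptr);
  }
  return out;
}
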