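#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed column-score matrix.
//
// S[i, j] holds the substitution score of position i of sequence/profile A
// against position j of B, so the same kernel serves residue-residue,
// profile-profile and nucleotide alignments.  A gap of length k costs
// gap_open + k * gap_extend (Biostrings convention).
//
// type: 0 = global (Needleman-Wunsch), 1 = local (Smith-Waterman),
//       2 = overlap (A global, free end gaps in B).
//
// Returns list(score, ai, bi): ai/bi are 1-based aligned indices with 0
// marking a gap in that sequence.
// [[Rcpp::export]]
List align_affine_cpp(NumericMatrix S, double gap_open, double gap_extend,
                      int type) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -std::numeric_limits<double>::max() / 4.0;
  const double go = gap_open + gap_extend;  // cost of opening a 1-long gap
  const double ge = gap_extend;

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in B (consume A/i)
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in A (consume B/j)
  // traceback: 0 none, 1 from M, 2 from X, 3 from Y (predecessor state)
  std::vector<unsigned char> tM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(go + (i - 1) * ge);
    tX[at(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    double free_gap = (type == 2) ? 0.0 : -(go + (j - 1) * ge);
    Y[at(0, j)] = free_gap;
    tY[at(0, j)] = (j == 1) ? 1 : 3;
  }

  double best = (type == 1) ? 0.0 : NEG;
  int bi = 0, bj = 0, bstate = 1;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double pm = dM; unsigned char tm = 1;
      if (dX > pm) { pm = dX; tm = 2; }
      if (dY > pm) { pm = dY; tm = 3; }
      double mval = pm + S(i - 1, j - 1);
      if (type == 1 && mval < 0.0) { mval = 0.0; tm = 0; }
      M[at(i, j)] = mval; tM[at(i, j)] = tm;
      // X: gap in B, consume A row i
      double xm = M[at(i - 1, j)] - go, xx = X[at(i - 1, j)] - ge;
      if (xm >= xx) { X[at(i, j)] = xm; tX[at(i, j)] = 1; }
      else          { X[at(i, j)] = xx; tX[at(i, j)] = 2; }
      // Y: gap in A, consume B col j
      double ym = M[at(i, j - 1)] - go, yy = Y[at(i, j - 1)] - ge;
      if (ym >= yy) { Y[at(i, j)] = ym; tY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = yy; tY[at(i, j)] = 3; }
      if (type == 1 && M[at(i, j)] >= best) {
        best = M[at(i, j)]; bi = i; bj = j; bstate = 1;
      }
    }
  }

  if (type == 0) {
    best = M[at(n, m)]; bi = n; bj = m; bstate = 1;
    if (X[at(n, m)] > best) { best = X[at(n, m)]; bstate = 2; }
    if (Y[at(n, m)] > best) { best = Y[at(n, m)]; bstate = 3; }
  } else if (type == 2) {
    // A fully aligned; best over last row (remaining B is a free end gap)
    best = NEG;
    for (int j = 0; j <= m; ++j) {
      double v = M[at(n, j)] > X[at(n, j)] ? M[at(n, j)] : X[at(n, j)];
      int st = M[at(n, j)] >= X[at(n, j)] ? 1 : 2;
      if (v > best) { best = v; bi = n; bj = j; bstate = st; }
    }
  }

  // traceback
  std::vector<int> ai, bjv;
  int i = bi, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    if (type == 1 && state == 1 && tM[at(i, j)] == 0) break;  // local start
    if (type == 2 && i == 0) break;  // leading B overhang is free
    if (state == 1) {
      if (i == 0 && j == 0) break;
      unsigned char t = tM[at(i, j)];
      ai.push_back(i); bjv.push_back(j);
      --i; --j; state = t;
      if (state == 0) state = 1;
    } else if (state == 2) {
      unsigned char t = tX[at(i, j)];
      ai.push_back(i); bjv.push_back(0);
      --i; state = t;
    } else {
      unsigned char t = tY[at(i, j)];
      ai.push_back(0); bjv.push_back(j);
      --j; state = t;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["score"] = best,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bjv.begin(), bjv.end()));
}
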