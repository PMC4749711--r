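#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch / Gotoh) alignment of two profiles under affine
// gap scoring. Profiles are 5 x L frequency matrices (rows A, C, G, T, gap).
// Column-column score: sum over base pairs f_a(x) f_b(y) * (x==y ? match :
// mismatch); profile gap mass contributes nothing. A gap run of length k
// costs gap_open + (k-1) * gap_ext. Traceback ties prefer diagonal, then up
// (gap in the second profile), then left.
// Returns an integer vector of edit ops (0 = diag, 1 = up, 2 = left) with the
// alignment score as attribute "score".
// [[Rcpp::export]]
IntegerVector cpp_nw_profile(NumericMatrix pa, NumericMatrix pb,
                             double match, double mismatch,
                             double gap_open, double gap_ext) {
  const int la = pa.ncol(), lb = pb.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  // substitution scores between columns
  NumericMatrix sub(la, lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          s += pa(x, i) * pb(y, j) * (x == y ? match : mismatch);
      sub(i, j) = s;
    }

  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG); // gap in b (consume a)
  std::vector<double> Y((la + 1) * (lb + 1), NEG); // gap in a (consume b)
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) X[idx(i, 0)] = gap_open + (i - 1) * gap_ext;
  for (int j = 1; j <= lb; ++j) Y[idx(0, j)] = gap_open + (j - 1) * gap_ext;

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)], dY = Y[idx(i - 1, j - 1)];
      double m = dM; if (dX > m) m = dX; if (dY > m) m = dY;
      M[idx(i, j)] = m + sub(i - 1, j - 1);

      double xo = M[idx(i - 1, j)] + gap_open;
      double xe = X[idx(i - 1, j)] + gap_ext;
      double xy = Y[idx(i - 1, j)] + gap_open;
      double x = xo; if (xe > x) x = xe; if (xy > x) x = xy;
      X[idx(i, j)] = x;

      double yo = M[idx(i, j - 1)] + gap_open;
      double yx = X[idx(i, j - 1)] + gap_open;
      double ye = Y[idx(i, j - 1)] + gap_ext;
      double y = yo; if (yx > y) y = yx; if (ye > y) y = ye;
      Y[idx(i, j)] = y;
    }
  }

  // traceback; state 0 = M, 1 = X, 2 = Y, preference M > X > Y on ties
  int i = la, j = lb;
  double fm = M[idx(i, j)], fx = X[idx(i, j)], fy = Y[idx(i, j)];
  double best = fm; int state = 0;
  if (fx > best) { best = fx; state = 1; }
  if (fy > best) { best = fy; state = 2; }
  double score = best;

  std::vector<int> ops;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      double tgt = M[idx(i, j)] - sub(i - 1, j - 1);
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)], dY = Y[idx(i - 1, j - 1)];
      if (dM >= tgt - 1e-9) state = 0;
      else if (dX >= tgt - 1e-9) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      double cur = X[idx(i, j)];
      if (i == 1 && j == 0) { --i; break; }
      if (M[idx(i - 1, j)] + gap_open >= cur - 1e-9) state = 0;
      else if (X[idx(i - 1, j)] + gap_ext >= cur - 1e-9) state = 1;
      else state = 2;
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 2; // only left moves remain
    } else {
      ops.push_back(2);
      double cur = Y[idx(i, j)];
      if (j == 1 && i == 0) { --j; break; }
      if (M[idx(i, j - 1)] + gap_open >= cur - 1e-9) state = 0;
      else if (X[idx(i, j - 1)] + gap_open >= cur - 1e-9) state = 1;
      else state = 2;
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) state = 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  IntegerVector out(ops.begin(), ops.end());
  out.attr("score") = score;
  return out;
}
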