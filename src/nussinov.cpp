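#include <Rcpp.h>
using namespace Rcpp;

// Nussinov-style hairpin folding with a stacking bonus. We maximise a
// positive score (pair weights GC 3, AT 2, GT 1, +1 per stacked adjacent
// pair) and report stability = -score, so more negative = more stable.
// min_loop unpaired bases are enforced between any pair (j - i > min_loop).
// Tables: F[i][j] best score of [i..j]; P[i][j] best score with (i,j)
// paired; Q[i][j] best score with (i,j) not paired together.
// Traceback prefers pairing, then leaving i unpaired, then j, then the
// leftmost split, giving a deterministic structure.

static inline int pw(char a, char b, int wgc, int wat, int wgt) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wgc;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return wat;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wgt;
  return 0;
}

// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int wgc, int wat, int wgt, int stack,
                  int min_loop) {
  const int n = seq.size();
  const int NEG = INT_MIN / 4;
  if (n == 0) return List::create(_["pairs"] = IntegerMatrix(0, 2), _["score"] = 0);

  std::vector<std::vector<int> > F(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, NEG));
  std::vector<std::vector<int> > Q(n, std::vector<int>(n, 0));

  auto Fat = [&](int i, int j) { return (i > j || i < 0 || j >= n) ? 0 : F[i][j]; };

  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // P: (i,j) paired
      int w = pw(seq[i], seq[j], wgc, wat, wgt);
      if (w > 0 && j - i > min_loop) {
        int innerP = (i + 1 <= j - 1 && P[i + 1][j - 1] > NEG / 2)
                     ? P[i + 1][j - 1] + stack : NEG;
        int innerQ = (i + 1 <= j - 1) ? Q[i + 1][j - 1] : 0;
        int inner = innerP > innerQ ? innerP : innerQ;
        if (i + 1 > j - 1) inner = 0;
        P[i][j] = w + inner;
      }
      // Q: (i,j) not paired with each other
      int q = Fat(i + 1, j);             // i unpaired
      int t = Fat(i, j - 1);             // j unpaired
      if (t > q) q = t;
      for (int k = i + 1; k < j; ++k) {  // bifurcation
        int v = F[i][k] + F[k + 1][j];
        if (v > q) q = v;
      }
      Q[i][j] = q;
      F[i][j] = (P[i][j] > q) ? P[i][j] : q;
    }
  }

  // traceback
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stk;
  stk.push_back(std::make_pair(0, n - 1));
  while (!stk.empty()) {
    int i = stk.back().first, j = stk.back().second;
    stk.pop_back();
    if (i >= j) continue;
    if (P[i][j] > NEG / 2 && P[i][j] == F[i][j]) {
      // prefer pairing (i,j); descend into the enclosed interval, where the
      // stacked continuation is itself preferred when it attains the optimum
      pairs.push_back(std::make_pair(i, j));
      int ii = i + 1, jj = j - 1;
      while (ii < jj) {
        int innerP = (P[ii][jj] > NEG / 2) ? P[ii][jj] + stack : NEG;
        int innerQ = Q[ii][jj];
        if (innerP >= innerQ && P[ii][jj] > NEG / 2) {
          pairs.push_back(std::make_pair(ii, jj));
          ++ii; --jj;
        } else {
          stk.push_back(std::make_pair(ii, jj)); // continue as Q-interval
          break;
        }
      }
      continue;
    }
    // Q-style choices
    int val = F[i][j];
    if (Fat(i + 1, j) == val) { stk.push_back(std::make_pair(i + 1, j)); continue; }
    if (Fat(i, j - 1) == val) { stk.push_back(std::make_pair(i, j - 1)); continue; }
    bool done = false;
    for (int k = i + 1; k < j && !done; ++k) {
      if (F[i][k] + F[k + 1][j] == val) {
        stk.push_back(std::make_pair(k + 1, j));
        stk.push_back(std::make_pair(i, k));
        done = true;
      }
    }
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["pairs"] = pm, _["score"] = F[0][n - 1]);
}
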