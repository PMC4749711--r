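#include <Rcpp.h>
using namespace Rcpp;

// Rule-based cloverleaf search. A candidate tRNA gene is laid out 5'->3' as
//   acceptor-5' (A bp) | linker 2 nt | D-stem 5' (D bp) | D-loop (LD nt) |
//   D-stem 3' | linker 1 nt | AC-stem 5' (5 bp) | AC-loop (7 nt) |
//   AC-stem 3' | variable loop (V nt) | T-stem 5' (5 bp) | T-loop (LT nt) |
//   T-stem 3' | acceptor-3' (A bp) | discriminator (1 nt)
// total length T = 2A + 2D + LD + LT + V + 31.
// Stems are scored per base pair (GC 3, AT 2, GT 1, else 0); the anticodon
// occupies the central 3 nt of the 7-nt anticodon loop.

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

struct Decomp {
  int start, T, A, D, LD, LT, V;
  int score;            // stem pair scores + motif bonus
  int acc_pairs, d_pairs, ac_pairs, t_pairs;
  int motif;            // 1 if T-loop contains the motif
  bool valid;
};

// score one decomposition anchored at s (0-based) in seq
static Decomp score_decomp(const std::string& seq, int s, int A, int D,
                           int LD, int LT, int V, const std::string& motif,
                           int motif_bonus) {
  Decomp d;
  d.start = s; d.A = A; d.D = D; d.LD = LD; d.LT = LT; d.V = V;
  d.T = 2 * A + 2 * D + LD + LT + V + 31;
  d.valid = true;

  int acc5 = s;                       // A bases
  int d5   = s + A + 2;               // D bases
  int d3   = d5 + D + LD;             // D bases
  int ac5  = d3 + D + 1;              // 5
  int ac3  = ac5 + 5 + 7;             // 5
  int t5   = ac3 + 5 + V;             // 5
  int tl   = t5 + 5;                  // LT
  int t3   = tl + LT;                 // 5
  int acc3 = t3 + 5;                  // A

  int sc = 0;
  d.acc_pairs = 0; d.d_pairs = 0; d.ac_pairs = 0; d.t_pairs = 0;
  for (int k = 0; k < A; ++k) {
    int ps = pair_score(seq[acc5 + k], seq[acc3 + A - 1 - k]);
    sc += ps; if (ps > 0) d.acc_pairs++;
  }
  for (int k = 0; k < D; ++k) {
    int ps = pair_score(seq[d5 + k], seq[d3 + D - 1 - k]);
    sc += ps; if (ps > 0) d.d_pairs++;
  }
  for (int k = 0; k < 5; ++k) {
    int ps = pair_score(seq[ac5 + k], seq[ac3 + 4 - k]);
    sc += ps; if (ps > 0) d.ac_pairs++;
  }
  for (int k = 0; k < 5; ++k) {
    int ps = pair_score(seq[t5 + k], seq[t3 + 4 - k]);
    sc += ps; if (ps > 0) d.t_pairs++;
  }
  d.motif = 0;
  int m = motif.size();
  for (int k = 0; k + m <= LT; ++k) {
    bool hit = true;
    for (int q = 0; q < m; ++q) if (seq[tl + k + q] != motif[q]) { hit = false; break; }
    if (hit) { d.motif = 1; break; }
  }
  d.score = sc + (d.motif ? motif_bonus : 0);
  return d;
}

static inline int min_pairs(int stem_len, double frac) {
  return (int)std::ceil(stem_len * frac - 1e-9);
}

// Enumerate decompositions at every start; keep, per start, the best-scoring
// one that passes the structural gates on the acceptor, D and T stems (the
// anticodon stem and T-loop motif are judged later as hard constraints).
// The acceptor gate depends only on (start, A, total length), so it is
// checked first and prunes almost all of the search space.
// Returns a matrix: start(1-based), T, A, D, LD, LT, V, score, acc_pairs,
// d_pairs, ac_pairs, t_pairs, motif.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_cloverleaf(std::string seq,
                                  int a_min, int a_max, int d_min, int d_max,
                                  int ld_min, int ld_max, int lt_min, int lt_max,
                                  int v_min, int v_max, int tot_min, int tot_max,
                                  std::string motif, int motif_bonus,
                                  double min_stem_frac) {
  int n = seq.size();
  std::vector<Decomp> best;
  for (int s = 0; s < n; ++s) {
    Decomp b; b.valid = false; b.score = -1;
    for (int A = a_min; A <= a_max; ++A) {
      for (int T = tot_min; T <= tot_max; ++T) {
        if (s + T > n) continue;
        // acceptor: 5' arm at s..s+A-1, 3' arm ends one short of the window
        // end (discriminator last)
        int acc3 = s + T - 1 - A;
        int accp = 0;
        for (int k = 0; k < A; ++k)
          if (pair_score(seq[s + k], seq[acc3 + A - 1 - k]) > 0) ++accp;
        if (accp < min_pairs(A, min_stem_frac)) continue;
        for (int D = d_min; D <= d_max; ++D)
          for (int LD = ld_min; LD <= ld_max; ++LD)
            for (int LT = lt_min; LT <= lt_max; ++LT) {
              int V = T - (2 * A + 2 * D + LD + LT + 31);
              if (V < v_min || V > v_max) continue;
              Decomp d = score_decomp(seq, s, A, D, LD, LT, V, motif, motif_bonus);
              if (d.d_pairs < min_pairs(D, min_stem_frac)) continue;
              if (d.t_pairs < min_pairs(5, min_stem_frac)) continue;
              if (d.score > b.score) { b = d; b.valid = true; }
            }
      }
    }
    if (b.valid) best.push_back(b);
  }
  IntegerMatrix out(best.size(), 13);
  for (size_t i = 0; i < best.size(); ++i) {
    const Decomp& d = best[i];
    out(i, 0) = d.start + 1; out(i, 1) = d.T; out(i, 2) = d.A; out(i, 3) = d.D;
    out(i, 4) = d.LD; out(i, 5) = d.LT; out(i, 6) = d.V; out(i, 7) = d.score;
    out(i, 8) = d.acc_pairs; out(i, 9) = d.d_pairs; out(i, 10) = d.ac_pairs;
    out(i, 11) = d.t_pairs; out(i, 12) = d.motif;
  }
  colnames(out) = CharacterVector::create("start", "total", "a_bp", "d_bp",
    "d_loop", "t_loop", "v_loop", "score", "acc_pairs", "d_pairs", "ac_pairs",
    "t_pairs", "motif");
  return out;
}

// Best decomposition of a whole window (T fixed = window length), no gates.
// Returns an empty matrix when no decomposition fits.
// [[Rcpp::export]]
IntegerMatrix cpp_fold_window(std::string window,
                              int a_min, int a_max, int d_min, int d_max,
                              int ld_min, int ld_max, int lt_min, int lt_max,
                              int v_min, int v_max,
                              std::string motif, int motif_bonus) {
  int T = window.size();
  Decomp b; b.valid = false; b.score = -1;
  for (int A = a_min; A <= a_max; ++A)
    for (int D = d_min; D <= d_max; ++D)
      for (int LD = ld_min; LD <= ld_max; ++LD)
        for (int LT = lt_min; LT <= lt_max; ++LT) {
          int V = T - (2 * A + 2 * D + LD + LT + 31);
          if (V < v_min || V > v_max) continue;
          Decomp d = score_decomp(window, 0, A, D, LD, LT, V, motif, motif_bonus);
          if (d.score > b.score) { b = d; b.valid = true; }
        }
  if (!b.valid) return IntegerMatrix(0, 13);
  IntegerMatrix out(1, 13);
  out(0, 0) = 1; out(0, 1) = b.T; out(0, 2) = b.A; out(0, 3) = b.D;
  out(0, 4) = b.LD; out(0, 5) = b.LT; out(0, 6) = b.V; out(0, 7) = b.score;
  out(0, 8) = b.acc_pairs; out(0, 9) = b.d_pairs; out(0, 10) = b.ac_pairs;
  out(0, 11) = b.t_pairs; out(0, 12) = b.motif;
  colnames(out) = CharacterVector::create("start", "total", "a_bp", "d_bp",
    "d_loop", "t_loop", "v_loop", "score", "acc_pairs", "d_pairs", "ac_pairs",
    "t_pairs", "motif");
  return out;
}
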