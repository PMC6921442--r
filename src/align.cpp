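#include <Rcpp.h>
using namespace Rcpp;

// Move codes shared with the R traceback:
//   0 none/stop, 1 diagonal, 2 vertical (consume seed row), 3 horizontal, 4 start
// Warp-DP pointer encoding: move + 10 * previous_state + 100 * pair_flag.

// Needleman-Wunsch accumulated matrix (global, gap-penalized).
// Returns V ((n+1) x (m+1)) and the move matrix. Tie order: diag > vert > horiz.
// [[Rcpp::export(name = ".dp_nwa")]]
List dp_nwa(NumericMatrix P, double gp) {
  int n = P.nrow(), m = P.ncol();
  NumericMatrix V(n + 1, m + 1);
  IntegerMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { V(i, 0) = i * gp; M(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { V(0, j) = j * gp; M(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = V(i - 1, j - 1) + P(i - 1, j - 1);
      int mv = 1;
      double v = V(i - 1, j) + gp;
      if (v > best) { best = v; mv = 2; }
      v = V(i, j - 1) + gp;
      if (v > best) { best = v; mv = 3; }
      V(i, j) = best; M(i, j) = mv;
    }
  }
  return List::create(_["V"] = V, _["move"] = M);
}

// Smith-Waterman accumulated matrix (local, zero-floored).
// [[Rcpp::export(name = ".dp_swa")]]
List dp_swa(NumericMatrix P, double gp) {
  int n = P.nrow(), m = P.ncol();
  NumericMatrix V(n + 1, m + 1);
  IntegerMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = V(i - 1, j - 1) + P(i - 1, j - 1);
      int mv = 1;
      double v = V(i - 1, j) + gp;
      if (v > best) { best = v; mv = 2; }
      v = V(i, j - 1) + gp;
      if (v > best) { best = v; mv = 3; }
      if (best <= 0) { best = 0; mv = 0; }
      V(i, j) = best; M(i, j) = mv;
    }
  }
  return List::create(_["V"] = V, _["move"] = M);
}

// Warping DP (DTW-style: no gaps; vertical/horizontal moves stretch one
// sequence by repeating an element). Within each 1-to-n warp run exactly one
// cell is the genuinely paired copy (scored P = pair similarity); the other
// copies are penalized insertions (scored W = warp similarity). The choice of
// paired copy is optimized by tracking pair-credit states:
//   state 1 = (col free,  row free)   state 2 = (col used, row free)
//   state 3 = (col free,  row used)   state 4 = (col used, row used)
// "used" means the run currently sharing that index already took its pair
// credit. local = false: paths run (1,1) -> (n,m) (borders -Inf, forcing
// first/last index matching). local = true: a fresh path may start at any
// cell (move 4), always on a pair column.
// [[Rcpp::export(name = ".dp_warp")]]
List dp_warp(NumericMatrix P, NumericMatrix W, bool local) {
  int n = P.nrow(), m = P.ncol();
  const double NEGINF = R_NegInf;
  NumericVector V(n * m * 4, NEGINF);
  IntegerVector PTR(n * m * 4, 0);
  // candidate helper: keep first-in-order candidate on ties (strict >)
  auto idx = [n, m](int i, int j, int s) { return (i - 1) + n * (j - 1) + n * m * s; };
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      double p = P(i - 1, j - 1), w = W(i - 1, j - 1);
      double best[4] = {NEGINF, NEGINF, NEGINF, NEGINF};
      int ptr[4] = {0, 0, 0, 0};
      auto offer = [&](int state, double val, int code) {
        if (val > best[state]) { best[state] = val; ptr[state] = code; }
      };
      // diagonal from (i-1, j-1)
      if (i > 1 && j > 1) {
        for (int s = 3; s >= 0; --s) {
          double pv = V[idx(i - 1, j - 1, s)];
          if (pv == NEGINF) continue;
          offer(3, pv + p, 1 + 10 * (s + 1) + 100);  // f = 1 -> state (1,1)
          offer(0, pv + w, 1 + 10 * (s + 1));        // f = 0 -> state (0,0)
        }
      }
      if (!local && i == 1 && j == 1) {      // diagonal from the (0,0) base
        offer(3, p, 1 + 100);
        offer(0, w, 1);
      }
      // vertical from (i-1, j): same column, fresh row
      if (i > 1) {
        for (int s = 3; s >= 0; --s) {
          double pv = V[idx(i - 1, j, s)];
          if (pv == NEGINF) continue;
          bool colUsed = (s == 1 || s == 3);   // states 2 and 4 (0-based 1, 3)
          if (!colUsed) offer(3, pv + p, 2 + 10 * (s + 1) + 100);
          offer(colUsed ? 1 : 0, pv + w, 2 + 10 * (s + 1));
        }
      }
      // horizontal from (i, j-1): same row, fresh column
      if (j > 1) {
        for (int s = 3; s >= 0; --s) {
          double pv = V[idx(i, j - 1, s)];
          if (pv == NEGINF) continue;
          bool rowUsed = (s == 2 || s == 3);   // states 3 and 4 (0-based 2, 3)
          if (!rowUsed) offer(3, pv + p, 3 + 10 * (s + 1) + 100);
          offer(rowUsed ? 2 : 0, pv + w, 3 + 10 * (s + 1));
        }
      }
      if (local) offer(3, p, 4 + 100);       // start a new local path: pair column
      for (int s = 0; s < 4; ++s) {
        V[idx(i, j, s)] = best[s];
        PTR[idx(i, j, s)] = ptr[s];
      }
    }
  }
  V.attr("dim") = IntegerVector::create(n, m, 4);
  PTR.attr("dim") = IntegerVector::create(n, m, 4);
  return List::create(_["V"] = V, _["ptr"] = PTR);
}
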