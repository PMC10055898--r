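#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment used throughout the package.
//
// Two entry points:
//  * .align_stats_cpp: linear-memory global alignment carrying
//    (matches, aligned pairs) along the optimal path, so percent identity is
//    available without any traceback storage. Used for identity statistics.
//  * .align_tb_cpp: full alignment with traceback (1 byte per cell), optional
//    free end gaps on either sequence; returns gapped strings and the end
//    coordinates of the aligned span. Used for TNR boundary location and for
//    profile merges in the progressive MSA.
//
// Tie-breaking is fixed (diagonal > gap-in-b > gap-in-a, open > extend) so
// results are deterministic.

static const double NEG_INF = -1e30;

struct Cell {
  double score;
  double matches; // identical aligned columns on the optimal path
  double pairs;   // aligned (non-gap) columns on the optimal path
};

// [[Rcpp::export(name = ".align_stats_cpp")]]
List align_stats_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<Cell> M(m + 1), X(m + 1), Y(m + 1), Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = {0.0, 0.0, 0.0};
  Xp[0] = {NEG_INF, 0, 0};
  Yp[0] = {NEG_INF, 0, 0};
  for (int j = 1; j <= m; ++j) {
    Yp[j] = {gap_open + gap_ext * (j - 1), 0, 0}; // leading gap in a
    Mp[j] = {NEG_INF, 0, 0};
    Xp[j] = {NEG_INF, 0, 0};
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = {NEG_INF, 0, 0};
    Y[0] = {NEG_INF, 0, 0};
    X[0] = {gap_open + gap_ext * (i - 1), 0, 0}; // leading gap in b
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool eq = (ai == b[j - 1]);
      const double s = eq ? match : mismatch;
      {
        const Cell *best = &Mp[j - 1];
        if (Xp[j - 1].score > best->score) best = &Xp[j - 1];
        if (Yp[j - 1].score > best->score) best = &Yp[j - 1];
        M[j] = {best->score + s, best->matches + (eq ? 1.0 : 0.0), best->pairs + 1.0};
      }
      {
        const double open = Mp[j].score + gap_open;
        const double openY = Yp[j].score + gap_open;
        const double ext = Xp[j].score + gap_ext;
        const double bo = (open >= openY) ? open : openY;
        if (bo >= ext) {
          const Cell &src = (open >= openY) ? Mp[j] : Yp[j];
          X[j] = {bo, src.matches, src.pairs};
        } else {
          X[j] = {ext, Xp[j].matches, Xp[j].pairs};
        }
      }
      {
        const double open = M[j - 1].score + gap_open;
        const double openX = X[j - 1].score + gap_open;
        const double ext = Y[j - 1].score + gap_ext;
        const double bo = (open >= openX) ? open : openX;
        if (bo >= ext) {
          const Cell &src = (open >= openX) ? M[j - 1] : X[j - 1];
          Y[j] = {bo, src.matches, src.pairs};
        } else {
          Y[j] = {ext, Y[j - 1].matches, Y[j - 1].pairs};
        }
      }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  const Cell *best = &Mp[m];
  if (Xp[m].score > best->score) best = &Xp[m];
  if (Yp[m].score > best->score) best = &Yp[m];
  const double cols = (double)n + (double)m - best->pairs;
  return List::create(_["score"] = best->score,
                      _["matches"] = best->matches,
                      _["pairs"] = best->pairs,
                      _["columns"] = cols);
}

// Packed move codes, one byte per cell:
//   bits 0-1: source of M (0=M, 1=X, 2=Y) at (i-1, j-1)
//   bit 2: X extended (from X above); bit 3: X opened from Y (else from M)
//   bit 4: Y extended (from Y left); bit 5: Y opened from X (else from M)
// [[Rcpp::export(name = ".align_tb_cpp")]]
List align_tb_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext,
                  bool free_a_ends, bool free_b_ends,
                  double max_cells) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double ncells = ((double)n + 1) * ((double)m + 1);
  if (ncells > max_cells)
    stop("alignment problem too large (%.0f cells, max_cells=%.0f)", ncells, max_cells);
  const size_t W = (size_t)m + 1;
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  std::vector<double> M(W), X(W), Y(W), Mp(W), Xp(W), Yp(W);
  // last-column scores per row (for free-end end-cell search)
  std::vector<double> colM(n + 1, NEG_INF), colX(n + 1, NEG_INF), colY(n + 1, NEG_INF);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Yp[j] = free_a_ends ? 0.0 : (gap_open + gap_ext * (j - 1));
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
  }
  colM[0] = Mp[m]; colX[0] = Xp[m]; colY[0] = Yp[m];
  if (m == 0) { colM[0] = 0.0; }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF; Y[0] = NEG_INF;
    X[0] = free_b_ends ? 0.0 : (gap_open + gap_ext * (i - 1));
    const char ai = a[i - 1];
    uint8_t *row = &tb[(size_t)i * W];
    for (int j = 1; j <= m; ++j) {
      const double s = (ai == b[j - 1]) ? match : mismatch;
      uint8_t code = 0;
      double best = Mp[j - 1]; int src = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; src = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; src = 2; }
      M[j] = best + s; code |= (uint8_t)src;
      {
        const double open = Mp[j] + gap_open, openY = Yp[j] + gap_open, ext = Xp[j] + gap_ext;
        const double bo = (open >= openY) ? open : openY;
        if (bo >= ext) { X[j] = bo; if (openY > open) code |= 8; }
        else { X[j] = ext; code |= 4; }
      }
      {
        const double open = M[j - 1] + gap_open, openX = X[j - 1] + gap_open, ext = Y[j - 1] + gap_ext;
        const double bo = (open >= openX) ? open : openX;
        if (bo >= ext) { Y[j] = bo; if (openX > open) code |= 32; }
        else { Y[j] = ext; code |= 16; }
      }
      row[j] = code;
    }
    colM[i] = M[m]; colX[i] = X[m]; colY[i] = Y[m];
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  // after the loop Mp/Xp/Yp hold row n

  // end cell: global -> (n, m); with free ends search last column / last row.
  // Ending at (i, m) with i < n leaves a trailing unaligned part of a (free
  // only when free_b_ends); ending at (n, j), j < m leaves trailing b (free
  // when free_a_ends).
  int ei = n, ej = m;
  double bestScore = std::max(colM[n], std::max(colX[n], colY[n]));
  if (free_b_ends) {
    for (int i = n - 1; i >= 0; --i) {
      const double v = std::max(colM[i], std::max(colX[i], colY[i]));
      if (v > bestScore) { bestScore = v; ei = i; ej = m; }
    }
  }
  if (free_a_ends) {
    for (int j = m - 1; j >= 0; --j) {
      const double v = std::max(Mp[j], std::max(Xp[j], Yp[j]));
      if (v > bestScore) { bestScore = v; ei = n; ej = j; }
    }
  }

  // choose start state at the end cell
  double sM, sX, sY;
  if (ei == n) { sM = Mp[ej]; sX = Xp[ej]; sY = Yp[ej]; }
  else { sM = colM[ei]; sX = colX[ei]; sY = colY[ei]; }
  int state = 0;
  { double bst = sM; if (sX > bst) { bst = sX; state = 1; } if (sY > bst) { state = 2; } }

  std::string ga, gb;
  ga.reserve((size_t)n + m); gb.reserve((size_t)n + m);
  double matches = 0, pairs = 0;
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    const uint8_t code = tb[(size_t)i * W + j];
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      pairs += 1; if (a[i - 1] == b[j - 1]) matches += 1;
      state = code & 3; --i; --j;
    } else if (state == 1) { // gap in b, consume a
      ga.push_back(a[i - 1]); gb.push_back('-');
      if (code & 4) state = 1; else state = (code & 8) ? 2 : 0;
      --i;
    } else { // gap in a, consume b
      ga.push_back('-'); gb.push_back(b[j - 1]);
      if (code & 16) state = 2; else state = (code & 32) ? 1 : 0;
      --j;
    }
  }
  while (i > 0) { ga.push_back(a[i - 1]); gb.push_back('-'); --i; }
  while (j > 0) { ga.push_back('-'); gb.push_back(b[j - 1]); --j; }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  // unaligned tails beyond the chosen end cell
  for (int k = ei; k < n; ++k) { ga.push_back(a[k]); gb.push_back('-'); }
  for (int k = ej; k < m; ++k) { ga.push_back('-'); gb.push_back(b[k]); }

  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = bestScore,
                      _["matches"] = matches, _["pairs"] = pairs,
                      _["a_end"] = ei, _["b_end"] = ej);
}
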