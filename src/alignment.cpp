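#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over integer-encoded
// sequences. Codes are 1-based row/column indices into `sub`. A gap of
// length L scores gap_open + L * gap_extend (both non-positive), i.e. the
// first gap character already pays the opening charge.
//
// local = true  -> Smith-Waterman (best-scoring local alignment)
// local = false -> Needleman-Wunsch (global alignment end to end)
//
// Path ops: 1 = aligned pair (both advance), 2 = gap in b (a advances),
// 3 = gap in a (b advances). Coordinates returned 1-based inclusive.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State { SM = 0, SE = 1, SF = 2 }; // E: gap in a, F: gap in b

// [[Rcpp::export]]
List cpp_pairwise_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                        double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend; // cost of opening (first gap char)
  const double ge = gap_extend;

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  // back pointers: previous state for each cell/state; 0..2, 3 = local start
  std::vector<signed char> bM((n + 1) * (m + 1), -1);
  std::vector<signed char> bE((n + 1) * (m + 1), -1);
  std::vector<signed char> bF((n + 1) * (m + 1), -1);

  const int W = m + 1;
  M[0] = 0.0;
  if (local) {
    for (int i = 0; i <= n; ++i) M[i * W] = 0.0;
    for (int j = 0; j <= m; ++j) M[j] = 0.0;
  } else {
    for (int j = 1; j <= m; ++j) {
      E[j] = gap_open + j * ge;
      bE[j] = (j == 1) ? SM : SE;
    }
    for (int i = 1; i <= n; ++i) {
      F[i * W] = gap_open + i * ge;
      bF[i * W] = (i == 1) ? SM : SF;
    }
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      const int cd = (i - 1) * W + (j - 1);
      const int cu = (i - 1) * W + j;
      const int cl = i * W + (j - 1);

      // M: consume a[i], b[j]
      double s = sub(ai, b[j - 1] - 1);
      double vM = M[cd], vE = E[cd], vF = F[cd];
      double pre = vM; signed char pb = SM;
      if (vE > pre) { pre = vE; pb = SE; }
      if (vF > pre) { pre = vF; pb = SF; }
      double mval = (pre == NEG_INF) ? NEG_INF : pre + s;
      if (local && mval < 0.0) { mval = 0.0; pb = 3; }
      M[c] = mval; bM[c] = pb;

      // E: gap in a (consume b[j])
      double openE = std::max(M[cl], F[cl]);
      double e1 = (openE == NEG_INF) ? NEG_INF : openE + go;
      double e2 = (E[cl] == NEG_INF) ? NEG_INF : E[cl] + ge;
      if (e1 >= e2) { E[c] = e1; bE[c] = (M[cl] >= F[cl]) ? SM : SF; }
      else          { E[c] = e2; bE[c] = SE; }

      // F: gap in b (consume a[i])
      double openF = std::max(M[cu], E[cu]);
      double f1 = (openF == NEG_INF) ? NEG_INF : openF + go;
      double f2 = (F[cu] == NEG_INF) ? NEG_INF : F[cu] + ge;
      if (f1 >= f2) { F[c] = f1; bF[c] = (M[cu] >= E[cu]) ? SM : SE; }
      else          { F[c] = f2; bF[c] = SF; }

      if (local && M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }

  int state;
  if (local) {
    state = SM;
    if (best <= 0.0) { // no positive-scoring segment
      return List::create(_["score"] = 0.0, _["path"] = IntegerVector(0),
                          _["astart"] = NA_INTEGER, _["aend"] = NA_INTEGER,
                          _["bstart"] = NA_INTEGER, _["bend"] = NA_INTEGER);
    }
  } else {
    const int c = n * W + m;
    best = M[c]; state = SM;
    if (E[c] > best) { best = E[c]; state = SE; }
    if (F[c] > best) { best = F[c]; state = SF; }
    bi = n; bj = m;
  }

  std::vector<int> ops;
  int i = bi, j = bj;
  while (true) {
    if (local) {
      if (state == SM && (i == 0 || j == 0)) break;
    } else {
      if (i == 0 && j == 0) break;
    }
    const int c = i * W + j;
    if (state == SM) {
      signed char pb = bM[c];
      ops.push_back(1); --i; --j;
      if (local && pb == 3) break; // local alignment start
      state = pb;
    } else if (state == SE) {
      signed char pb = bE[c];
      ops.push_back(3); --j;
      state = pb;
    } else {
      signed char pb = bF[c];
      ops.push_back(2); --i;
      state = pb;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = best,
                      _["path"] = IntegerVector(ops.begin(), ops.end()),
                      _["astart"] = i + 1, _["aend"] = bi,
                      _["bstart"] = j + 1, _["bend"] = bj);
}

// Global affine alignment over a precomputed column-score matrix S
// (rows = columns of profile A, cols = columns of profile B). Used for
// profile-profile alignment in the progressive MSA. Same path encoding.
// [[Rcpp::export]]
IntegerVector cpp_matrix_align(NumericMatrix S, double gap_open,
                               double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int W = m + 1;

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> bM((n + 1) * (m + 1), -1);
  std::vector<signed char> bE((n + 1) * (m + 1), -1);
  std::vector<signed char> bF((n + 1) * (m + 1), -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) { E[j] = gap_open + j * ge; bE[j] = (j == 1) ? SM : SE; }
  for (int i = 1; i <= n; ++i) { F[i * W] = gap_open + i * ge; bF[i * W] = (i == 1) ? SM : SF; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, cd = (i - 1) * W + (j - 1),
                cu = (i - 1) * W + j, cl = i * W + (j - 1);
      double pre = M[cd]; signed char pb = SM;
      if (E[cd] > pre) { pre = E[cd]; pb = SE; }
      if (F[cd] > pre) { pre = F[cd]; pb = SF; }
      M[c] = (pre == NEG_INF) ? NEG_INF : pre + S(i - 1, j - 1);
      bM[c] = pb;

      double openE = std::max(M[cl], F[cl]);
      double e1 = (openE == NEG_INF) ? NEG_INF : openE + go;
      double e2 = (E[cl] == NEG_INF) ? NEG_INF : E[cl] + ge;
      if (e1 >= e2) { E[c] = e1; bE[c] = (M[cl] >= F[cl]) ? SM : SF; }
      else          { E[c] = e2; bE[c] = SE; }

      double openF = std::max(M[cu], E[cu]);
      double f1 = (openF == NEG_INF) ? NEG_INF : openF + go;
      double f2 = (F[cu] == NEG_INF) ? NEG_INF : F[cu] + ge;
      if (f1 >= f2) { F[c] = f1; bF[c] = (M[cu] >= E[cu]) ? SM : SE; }
      else          { F[c] = f2; bF[c] = SF; }
    }
  }

  int i = n, j = m, state = SM;
  const int cend = n * W + m;
  double best = M[cend];
  if (E[cend] > best) { best = E[cend]; state = SE; }
  if (F[cend] > best) { best = F[cend]; state = SF; }

  std::vector<int> ops;
  while (!(i == 0 && j == 0)) {
    const int c = i * W + j;
    if (state == SM)      { signed char pb = bM[c]; ops.push_back(1); --i; --j; state = pb; }
    else if (state == SE) { signed char pb = bE[c]; ops.push_back(3); --j; state = pb; }
    else                  { signed char pb = bF[c]; ops.push_back(2); --i; state = pb; }
  }
  std::reverse(ops.begin(), ops.end());
  return IntegerVector(ops.begin(), ops.end());
}

// Score-only Smith-Waterman over all pairs of two sequence sets
// (integer-encoded, 1-based codes). Rolling-row DP, no traceback.
// [[Rcpp::export]]
NumericMatrix cpp_sw_score_matrix(List a, List b, NumericMatrix sub,
                                  double gap_open, double gap_extend) {
  const int nA = a.size(), nB = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  NumericMatrix out(nA, nB);
  std::vector<std::vector<int> > av(nA), bv(nB);
  for (int i = 0; i < nA; ++i) av[i] = as<std::vector<int> >(a[i]);
  for (int j = 0; j < nB; ++j) bv[j] = as<std::vector<int> >(b[j]);
  for (int i = 0; i < nA; ++i) {
    const std::vector<int>& x = av[i];
    for (int j = 0; j < nB; ++j) {
      const std::vector<int>& y = bv[j];
      const int n = (int)x.size(), m = (int)y.size();
      // H[c] = best score ending at column c (any state, clamped at 0),
      // F[c] = best ending in a vertical gap; E tracked along the row
      std::vector<double> H(m + 1, 0.0), F(m + 1, NEG_INF);
      double best = 0.0;
      for (int r = 1; r <= n; ++r) {
        double diag = 0.0;       // H[r-1][c-1], starts at H[r-1][0] = 0
        double E = NEG_INF;      // E[r][c]
        double Hleft = 0.0;      // H[r][c-1]
        const int xr = x[r - 1] - 1;
        for (int c = 1; c <= m; ++c) {
          const double hup = H[c];                 // H[r-1][c]
          F[c] = std::max(hup + go, F[c] + ge);
          E = std::max(Hleft + go, E + ge);
          double h = diag + sub(xr, y[c - 1] - 1);
          if (E > h) h = E;
          if (F[c] > h) h = F[c];
          if (h < 0.0) h = 0.0;
          diag = hup;
          H[c] = h;
          Hleft = h;
          if (h > best) best = h;
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}
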