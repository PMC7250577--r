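// Affine-gap dynamic programming on a generic position x position score
// matrix. One kernel serves residue-residue, profile-residue and
// profile-profile alignment: the caller supplies S[i, j] = score of pairing
// row unit i with column unit j.
//
// Gap convention: a gap of length L costs gap_open + gap_extend * L.
// Tie-break contract (documented in ?globalAlign): at equal score prefer
// (1) pairing the two units, (2) consuming a row unit against a gap,
// (3) consuming a column unit against a gap. Tracebacks are bit-stable.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// op codes emitted in the traceback path
static const int OP_DIAG = 0; // consume one row unit and one column unit
static const int OP_UP = 1;   // consume a row unit against a gap
static const int OP_LEFT = 2; // consume a column unit against a gap

// [[Rcpp::export]]
List cpp_affine_global(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double gopen = gap_open + gap_extend; // cost of the first gap unit
  // DP matrices: M ends in a pair, U ends in a row-vs-gap, L ends in col-vs-gap
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> U((n + 1) * (m + 1), NEG_INF);
  std::vector<double> L((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) U[at(i, 0)] = -(gap_open + gap_extend * i);
  for (int j = 1; j <= m; ++j) L[at(0, j)] = -(gap_open + gap_extend * j);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j), di = at(i - 1, j - 1);
      double best = M[di];
      if (U[di] > best) best = U[di];
      if (L[di] > best) best = L[di];
      M[ij] = best + S(i - 1, j - 1);
      const int up = at(i - 1, j);
      double u = M[up] - gopen;
      if (U[up] - gap_extend > u) u = U[up] - gap_extend;
      if (L[up] - gopen > u) u = L[up] - gopen;
      U[ij] = u;
      const int lf = at(i, j - 1);
      double l = M[lf] - gopen;
      if (U[lf] - gopen > l) l = U[lf] - gopen;
      if (L[lf] - gap_extend > l) l = L[lf] - gap_extend;
      L[ij] = l;
    }
  }
  // traceback with fixed state priority M > U > L
  int i = n, j = m;
  int state;
  double score;
  {
    const int ij = at(n, m);
    if (M[ij] >= U[ij] && M[ij] >= L[ij]) { state = 0; score = M[ij]; }
    else if (U[ij] >= L[ij]) { state = 1; score = U[ij]; }
    else { state = 2; score = L[ij]; }
  }
  std::vector<int> ops;
  ops.reserve(n + m);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error in global alignment");
      const int di = at(i - 1, j - 1), ij = at(i, j);
      const double need = M[ij] - S(i - 1, j - 1);
      ops.push_back(OP_DIAG);
      if (std::abs(M[di] - need) < eps) state = 0;
      else if (std::abs(U[di] - need) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (i == 0) { state = 2; continue; }
      const int up = at(i - 1, j), ij = at(i, j);
      ops.push_back(OP_UP);
      if (std::abs(M[up] - gopen - U[ij]) < eps) state = 0;
      else if (std::abs(U[up] - gap_extend - U[ij]) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      if (j == 0) { state = 1; continue; }
      const int lf = at(i, j - 1), ij = at(i, j);
      ops.push_back(OP_LEFT);
      if (std::abs(M[lf] - gopen - L[ij]) < eps) state = 0;
      else if (std::abs(U[lf] - gopen - L[ij]) < eps) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}

// Local (Smith-Waterman style) affine alignment on a score matrix.
// The first strictly-better cell wins, so the reported envelope is the
// earliest maximal segment (deterministic tie-break: smallest start).
// [[Rcpp::export]]
List cpp_affine_local(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double gopen = gap_open + gap_extend;
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> U((n + 1) * (m + 1), NEG_INF);
  std::vector<double> L((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j), di = at(i - 1, j - 1);
      double mm = M[di];
      if (U[di] > mm) mm = U[di];
      if (L[di] > mm) mm = L[di];
      mm += S(i - 1, j - 1);
      if (mm < 0.0) mm = 0.0; // restart a fresh segment
      M[ij] = mm;
      const int up = at(i - 1, j);
      double u = M[up] - gopen;
      if (U[up] - gap_extend > u) u = U[up] - gap_extend;
      U[ij] = u;
      const int lf = at(i, j - 1);
      double l = M[lf] - gopen;
      if (L[lf] - gap_extend > l) l = L[lf] - gap_extend;
      L[ij] = l;
      if (mm > best + 1e-12) { best = mm; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["row_start"] = 0, _["row_end"] = 0,
                        _["col_start"] = 0, _["col_end"] = 0);
  }
  // trace back to the segment start; a maximal local segment begins and
  // ends with a paired cell, so track the earliest M-state visit
  int i = bi, j = bj, state = 0;
  int si = bi, sj = bj;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      si = i; sj = j; // this pair belongs to the segment
      const double need = M[at(i, j)] - S(i - 1, j - 1);
      if (need < eps) { break; } // the 0-restart: segment starts here
      const int di = at(i - 1, j - 1);
      if (std::abs(M[di] - need) < eps) state = 0;
      else if (U[di] > NEG_INF && std::abs(U[di] - need) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const int ij = at(i, j), up = at(i - 1, j);
      if (std::abs(M[up] - gopen - U[ij]) < eps) state = 0;
      else state = 1;
      --i;
    } else {
      const int ij = at(i, j), lf = at(i, j - 1);
      if (std::abs(M[lf] - gopen - L[ij]) < eps) state = 0;
      else state = 2;
      --j;
    }
  }
  return List::create(_["score"] = best,
                      _["row_start"] = si, _["row_end"] = bi,
                      _["col_start"] = sj, _["col_end"] = bj);
}
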