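#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// A gap of length L costs gap_open + L * gap_extend.
// Tie-breaking is deterministic: on equal score prefer the match/mismatch state,
// then the delete state (gap in sequence b), then the insert state (gap in a).
//
// a, b: 0-based integer codes into the rows/cols of `score`.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix score,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of the first gap position
  const double ge = gap_extend;

  // state 0 = M (a[i-1] ~ b[j-1]), 1 = X (gap in b), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tM((n + 1) * (m + 1), -1);
  std::vector<signed char> tX((n + 1) * (m + 1), -1);
  std::vector<signed char> tY((n + 1) * (m + 1), -1);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + ge * i);
    tX[idx(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + ge * j);
    tY[idx(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = idx(i, j);
      // M: best of the three at (i-1, j-1), prefer M > X > Y on ties
      {
        const int p = idx(i - 1, j - 1);
        double best = M[p]; signed char st = 0;
        if (X[p] > best) { best = X[p]; st = 1; }
        if (Y[p] > best) { best = Y[p]; st = 2; }
        if (best > NEG_INF / 2) {
          M[c] = best + score(a[i - 1], b[j - 1]);
          tM[c] = st;
        }
      }
      // X: gap in b, consume a[i-1]
      {
        const int p = idx(i - 1, j);
        double best = (M[p] > NEG_INF / 2) ? M[p] - go : NEG_INF; signed char st = 0;
        double vx = (X[p] > NEG_INF / 2) ? X[p] - ge : NEG_INF;
        if (vx > best) { best = vx; st = 1; }
        double vy = (Y[p] > NEG_INF / 2) ? Y[p] - go : NEG_INF;
        if (vy > best) { best = vy; st = 2; }
        if (best > NEG_INF / 2) { X[c] = best; tX[c] = st; }
      }
      // Y: gap in a, consume b[j-1]
      {
        const int p = idx(i, j - 1);
        double best = (M[p] > NEG_INF / 2) ? M[p] - go : NEG_INF; signed char st = 0;
        double vx = (X[p] > NEG_INF / 2) ? X[p] - go : NEG_INF;
        if (vx > best) { best = vx; st = 1; }
        double vy = (Y[p] > NEG_INF / 2) ? Y[p] - ge : NEG_INF;
        if (vy > best) { best = vy; st = 2; }
        if (best > NEG_INF / 2) { Y[c] = best; tY[c] = st; }
      }
    }
  }

  const int e = idx(n, m);
  double best = M[e]; int state = 0;
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }

  // traceback
  std::vector<int> ops;  // 0 = match column, 1 = gap in b, 2 = gap in a
  int i = n, j = m;
  while (i > 0 || j > 0) {
    ops.push_back(state);
    signed char prev;
    if (state == 0)      { prev = tM[idx(i, j)]; --i; --j; }
    else if (state == 1) { prev = tX[idx(i, j)]; --i; }
    else                 { prev = tY[idx(i, j)]; --j; }
    state = prev;
  }
  std::reverse(ops.begin(), ops.end());

  const int L = ops.size();
  IntegerVector ai(L), bi(L);  // 1-based positions, NA for gap
  int pa = 0, pb = 0;
  for (int k = 0; k < L; ++k) {
    if (ops[k] == 0)      { ai[k] = ++pa; bi[k] = ++pb; }
    else if (ops[k] == 1) { ai[k] = ++pa; bi[k] = NA_INTEGER; }
    else                  { ai[k] = NA_INTEGER; bi[k] = ++pb; }
  }

  return List::create(_["score"] = best, _["a_pos"] = ai, _["b_pos"] = bi);
}
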