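#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh), global (Needleman-Wunsch style) or
// local (Smith-Waterman style). A gap of length k costs gap_open + k * gap_ext.
// Sequences arrive as 0-based integer codes into the substitution matrix.
// Returns the optimal score and one optimal alignment as paired index vectors
// (1-based positions, NA at gap columns). Ties are broken deterministically:
// diagonal (match state) over gap-in-b over gap-in-a.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align_int")]]
List gotoh_align_int(IntegerVector a, IntegerVector b, NumericMatrix sub,
                     double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback codes: for M: 0=start/zero, 1=M, 2=X, 3=Y (at i-1,j-1)
  //                  for X: 1=M, 2=X, 3=Y (at i-1,j)
  //                  for Y: 1=M, 2=X, 3=Y (at i,j-1)
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = local ? NEG_INF : -(gap_open + i * gap_ext);
    tX[i * W] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = local ? NEG_INF : -(gap_open + j * gap_ext);
    tY[j] = (j == 1) ? 1 : 3;
  }

  double best = 0.0;
  int bi = 0, bj = 0;  // best cell for local traceback

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // match state
      double prev = M[dg];
      unsigned char tb = 1;
      if (X[dg] > prev) { prev = X[dg]; tb = 2; }
      if (Y[dg] > prev) { prev = Y[dg]; tb = 3; }
      if (local && 0.0 > prev) { prev = 0.0; tb = 0; }
      double s = sub(a[i - 1], b[j - 1]);
      M[c] = (prev <= NEG_INF / 2) ? NEG_INF : prev + s;
      tM[c] = tb;
      // gap in b (consume a_i)
      double x = M[up] - (gap_open + gap_ext);
      unsigned char tbx = 1;
      if (X[up] - gap_ext > x) { x = X[up] - gap_ext; tbx = 2; }
      if (Y[up] - (gap_open + gap_ext) > x) {
        x = Y[up] - (gap_open + gap_ext); tbx = 3;
      }
      X[c] = x; tX[c] = tbx;
      // gap in a (consume b_j)
      double y = M[lf] - (gap_open + gap_ext);
      unsigned char tby = 1;
      if (X[lf] - (gap_open + gap_ext) > y) {
        y = X[lf] - (gap_open + gap_ext); tby = 2;
      }
      if (Y[lf] - gap_ext > y) { y = Y[lf] - gap_ext; tby = 3; }
      Y[c] = y; tY[c] = tby;

      if (local && M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }

  double score;
  int i, j, state;  // state: 1=M, 2=X, 3=Y
  if (local) {
    score = best;
    i = bi; j = bj; state = 1;
    if (best <= 0.0) {  // no positive-scoring local alignment
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    }
  } else {
    const int c = n * W + m;
    score = M[c]; state = 1;
    if (X[c] > score) { score = X[c]; state = 2; }
    if (Y[c] > score) { score = Y[c]; state = 3; }
    i = n; j = m;
  }

  std::vector<int> ai, bi_v;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 1) {
      unsigned char tb = tM[c];
      ai.push_back(i); bi_v.push_back(j);
      --i; --j;
      if (local && tb == 0) break;  // alignment started at this column
      state = tb;
    } else if (state == 2) {
      ai.push_back(i); bi_v.push_back(NA_INTEGER);
      unsigned char tb = tX[c];
      --i; state = tb;
    } else {
      ai.push_back(NA_INTEGER); bi_v.push_back(j);
      unsigned char tb = tY[c];
      --j; state = tb;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_v.begin(), bi_v.end());
  return List::create(_["score"] = score, _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi_v));
}
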