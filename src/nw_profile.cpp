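#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment (Gotoh affine gaps) over a
// precomputed column-pair score matrix. Returns the aligned column
// index paths (1-based; 0 marks a gap column). Tie-breaking is fixed
// (diagonal > gap-in-B > gap-in-A) so the alignment is deterministic.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix score, double gap_open, double gap_ext) {
  const int n = score.nrow(), m = score.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in columns of B (A advances); Y: gap in columns of A.
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_ext * (i - 1);
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_ext * (j - 1);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = std::max(M(i - 1, j - 1),
                    std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + score(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) - gap_open, X(i - 1, j) - gap_ext);
      Y(i, j) = std::max(M(i, j - 1) - gap_open, Y(i, j - 1) - gap_ext);
    }
  }
  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  double endM = M(n, m), endX = X(n, m), endY = Y(n, m);
  if (endM >= endX && endM >= endY) state = 0;
  else if (endX >= endY) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double pm = M(i - 1, j - 1), px = X(i - 1, j - 1),
             py = Y(i - 1, j - 1);
      if (pm >= px && pm >= py) state = 0;
      else if (px >= py) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = (M(i - 1, j) - gap_open >= X(i - 1, j) - gap_ext) ? 0 : 1;
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = (M(i, j - 1) - gap_open >= Y(i, j - 1) - gap_ext) ? 0 : 2;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = std::max(endM, std::max(endX, endY)));
}
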