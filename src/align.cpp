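#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP) with full traceback.
// A gap run of length k scores gap_open + (k-1) * gap_extend; switching the
// gapped sequence opens a new gap. Substitution scores come from a 256x256
// lookup indexed by (unsigned char) residue codes. Tie-breaking is
// deterministic: at every cell the states are preferred in the order
// match/mismatch (diagonal) > gap-in-b (up) > gap-in-a (left).
//
// States: 0 = M (diagonal), 1 = X (consume a, gap in b), 2 = Y (consume b).

// [[Rcpp::export]]
List gotoh_align(std::string a, std::string b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // DP matrices, (n+1) x (m+1), flattened.
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  // Traceback: predecessor state for each state at each cell.
  std::vector<signed char> pM(M.size(), -1), pX = pM, pY = pM;
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const unsigned char ca = (unsigned char)a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const unsigned char cb = (unsigned char)b[j - 1];
      const double s = sub((int)ca, (int)cb);
      // M: diagonal from best of the three, preference M > X > Y.
      {
        const int d = at(i - 1, j - 1);
        double best = M[d];
        signed char p = 0;
        if (X[d] > best) { best = X[d]; p = 1; }
        if (Y[d] > best) { best = Y[d]; p = 2; }
        if (best > NEG) { M[at(i, j)] = best + s; pM[at(i, j)] = p; }
      }
      // X: gap in b (move up), open from M or Y, extend from X.
      {
        const int u = at(i - 1, j);
        double best = M[u] + gap_open;
        signed char p = 0;
        if (X[u] + gap_extend > best) { best = X[u] + gap_extend; p = 1; }
        if (Y[u] + gap_open > best) { best = Y[u] + gap_open; p = 2; }
        X[at(i, j)] = best;
        pX[at(i, j)] = p;
      }
      // Y: gap in a (move left).
      {
        const int l = at(i, j - 1);
        double best = M[l] + gap_open;
        signed char p = 0;
        if (X[l] + gap_open > best) { best = X[l] + gap_open; p = 1; }
        if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; p = 2; }
        Y[at(i, j)] = best;
        pY[at(i, j)] = p;
      }
    }
  }

  // Final state, preference M > X > Y.
  const int e = at(n, m);
  double score = M[e];
  int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  // Traceback.
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char p;
    if (state == 0) {
      p = pM[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      p = pX[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      p = pY[at(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
    state = p;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
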