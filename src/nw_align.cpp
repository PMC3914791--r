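#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh algorithm),
// end gaps penalized. Used by the all-pairs Ks stage, where the S4
// overhead of extracting aligned strings from R-level alignment objects
// dominates runtime. Scoring follows the usual convention:
// gap cost(len) = gap_open + len * gap_ext.
//
// score: substitution matrix with dimnames giving the residue alphabet.
// Characters absent from the alphabet score `mismatch`.

// [[Rcpp::export(name = ".nw_align_pair")]]
List nw_align_pair(std::string a, std::string b, NumericMatrix score,
                   CharacterVector alphabet, double gap_open,
                   double gap_ext, double mismatch = -4.0) {
  const int n = a.size(), m = b.size();
  std::vector<int> code(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    code[(unsigned char) CHAR(STRING_ELT(alphabet, k))[0]] = k;
  }
  const double NEG = -1e30;
  // M: a[i] aligned to b[j]; X: gap in b (a consumed); Y: gap in a
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + i * gap_ext);
    tbX[at(i, 0)] = 1;  // extended
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + j * gap_ext);
    tbY[at(0, j)] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    const int ca = code[(unsigned char) a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int cb = code[(unsigned char) b[j - 1]];
      const double s = (ca >= 0 && cb >= 0) ? score(ca, cb) : mismatch;
      // M
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      double best = m0; unsigned char tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M[at(i, j)] = best + s;
      tbM[at(i, j)] = tb;
      // X: gap in b, consume a[i]
      double opening = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) -
                       (gap_open + gap_ext);
      double extending = X[at(i - 1, j)] - gap_ext;
      if (opening >= extending) {
        X[at(i, j)] = opening;
        tbX[at(i, j)] = (M[at(i - 1, j)] >= Y[at(i - 1, j)]) ? 0 : 2;
      } else {
        X[at(i, j)] = extending;
        tbX[at(i, j)] = 1;
      }
      // Y: gap in a, consume b[j]
      double openingY = std::max(M[at(i, j - 1)], X[at(i, j - 1)]) -
                        (gap_open + gap_ext);
      double extendingY = Y[at(i, j - 1)] - gap_ext;
      if (openingY >= extendingY) {
        Y[at(i, j)] = openingY;
        tbY[at(i, j)] = (M[at(i, j - 1)] >= X[at(i, j - 1)]) ? 0 : 2;
      } else {
        Y[at(i, j)] = extendingY;
        tbY[at(i, j)] = 1;
      }
    }
  }

  // traceback from the best terminal state
  int i = n, j = m;
  double bm = M[at(n, m)], bx = X[at(n, m)], by = Y[at(n, m)];
  int state = 0;  // 0 = M, 1 = X, 2 = Y
  double bestScore = bm;
  if (bx > bestScore) { bestScore = bx; state = 1; }
  if (by > bestScore) { bestScore = by; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      state = tb;
    } else if (state == 1) {
      unsigned char tb = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      state = (tb == 1) ? 1 : (tb == 0 ? 0 : 2);
    } else {
      unsigned char tb = tbY[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      state = (tb == 1) ? 2 : (tb == 0 ? 0 : 1);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = bestScore);
}
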