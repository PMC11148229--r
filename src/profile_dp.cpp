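#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap dynamic programming between two alignment profiles.
// `S` holds the pre-computed column-vs-column substitution scores
// (L1 x L2). End gaps are free (semi-global), so fragments embed into
// longer profiles without paying for the unmatched flanks.
//
// Returns two integer vectors of equal length: for each merged column the
// 1-based source column in profile 1 / profile 2, or 0 for a gap.
// [[Rcpp::export(name = ".profile_dp")]]
List profile_dp(NumericMatrix S, double gap_open, double gap_ext) {
  const int L1 = S.nrow(), L2 = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(L1 + 1, L2 + 1), X(L1 + 1, L2 + 1), Y(L1 + 1, L2 + 1);
  IntegerMatrix tM(L1 + 1, L2 + 1), tX(L1 + 1, L2 + 1), tY(L1 + 1, L2 + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= L1; ++i) {         // leading gaps in profile 2: free
    M(i, 0) = NEG; Y(i, 0) = NEG; X(i, 0) = 0.0; tX(i, 0) = 1;
  }
  for (int j = 1; j <= L2; ++j) {         // leading gaps in profile 1: free
    M(0, j) = NEG; X(0, j) = NEG; Y(0, j) = 0.0; tY(0, j) = 2;
  }

  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      // M: consume a column from both profiles
      double m0 = M(i - 1, j - 1), m1 = X(i - 1, j - 1), m2 = Y(i - 1, j - 1);
      int tb = 0; double best = m0;
      if (m1 > best) { best = m1; tb = 1; }
      if (m2 > best) { best = m2; tb = 2; }
      M(i, j) = best + S(i - 1, j - 1); tM(i, j) = tb;

      // X: gap column in profile 2 (consume profile-1 column i);
      // free when profile 2 is exhausted (trailing end gap)
      double opn = (j == L2) ? 0.0 : gap_open + gap_ext;
      double ext = (j == L2) ? 0.0 : gap_ext;
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - opn;
      double xe = X(i - 1, j) - ext;
      if (xe >= xo) { X(i, j) = xe; tX(i, j) = 1; }
      else { X(i, j) = xo; tX(i, j) = (M(i - 1, j) >= Y(i - 1, j)) ? 0 : 2; }

      // Y: gap column in profile 1 (consume profile-2 column j)
      double opn2 = (i == L1) ? 0.0 : gap_open + gap_ext;
      double ext2 = (i == L1) ? 0.0 : gap_ext;
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - opn2;
      double ye = Y(i, j - 1) - ext2;
      if (ye >= yo) { Y(i, j) = ye; tY(i, j) = 2; }
      else { Y(i, j) = yo; tY(i, j) = (M(i, j - 1) >= X(i, j - 1)) ? 0 : 1; }
    }
  }

  int state = 0; double best = M(L1, L2);
  if (X(L1, L2) > best) { best = X(L1, L2); state = 1; }
  if (Y(L1, L2) > best) { best = Y(L1, L2); state = 2; }

  std::vector<int> p1, p2;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      p1.push_back(i); p2.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      p1.push_back(i); p2.push_back(0); --i; state = prev;
    } else {
      int prev = tY(i, j);
      p1.push_back(0); p2.push_back(j); --j; state = prev;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["p1"] = wrap(p1), _["p2"] = wrap(p2),
                      _["score"] = best);
}
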