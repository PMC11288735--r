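// Banded Needleman-Wunsch global alignment with affine gap costs.
// Cost model matches the R-level aligner: a gap run of length k costs
// open + k * extend; N never matches anything. The band is a window of
// diagonal offsets around the main diagonal (shifted by the length
// difference); for near-identical sequences, such as retroelement copies
// differing mostly by substitutions, a modest band is exact.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".bandedAlignCpp")]]
List bandedAlignCpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gapOpen, double gapExtend, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // diagonal offsets d = j - i covered by the band
  const int dlo = std::min(0, m - n) - band;
  const int dhi = std::max(0, m - n) + band;
  const int W = dhi - dlo + 1;
  if (static_cast<double>(n + 1) * W > 3e8)
    stop("banded alignment window too large (%d x %d); "
         "use the full aligner or similar-length sequences", n + 1, W);

  std::vector<double> M((n + 1) * W, NEG_INF),
                      X((n + 1) * W, NEG_INF),   // gap in b (a consumed)
                      Y((n + 1) * W, NEG_INF);   // gap in a (b consumed)
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
                           tY((n + 1) * W, -1);
  auto idx = [&](int i, int j) { return i * W + (j - i - dlo); };
  auto inBand = [&](int i, int j) {
    int d = j - i;
    return j >= 0 && j <= m && d >= dlo && d <= dhi;
  };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (!inBand(0, j)) continue;
    Y[idx(0, j)] = -(gapOpen + gapExtend * j);
    tY[idx(0, j)] = (j == 1) ? 0 : 2;  // came from M(0,0) or Y
  }
  for (int i = 1; i <= n; ++i) {
    if (inBand(i, 0)) {
      X[idx(i, 0)] = -(gapOpen + gapExtend * i);
      tX[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = std::max(1, i + dlo); j <= std::min(m, i + dhi); ++j) {
      const int k = idx(i, j);
      // M: diagonal move
      if (inBand(i - 1, j - 1)) {
        const int kd = idx(i - 1, j - 1);
        double best = M[kd]; signed char t = 0;
        if (X[kd] > best) { best = X[kd]; t = 1; }
        if (Y[kd] > best) { best = Y[kd]; t = 2; }
        if (best > NEG_INF / 2) {
          char ca = a[i - 1], cb = b[j - 1];
          bool isMatch = (ca == cb) && ca != 'N' && ca != 'n';
          M[k] = best + (isMatch ? match : mismatch);
          tM[k] = t;
        }
      }
      // X: consume a[i-1], gap in b
      if (inBand(i - 1, j)) {
        const int ku = idx(i - 1, j);
        double fromM = (M[ku] > NEG_INF / 2) ? M[ku] - gapOpen - gapExtend
                                             : NEG_INF;
        double fromX = (X[ku] > NEG_INF / 2) ? X[ku] - gapExtend : NEG_INF;
        double fromY = (Y[ku] > NEG_INF / 2) ? Y[ku] - gapOpen - gapExtend
                                             : NEG_INF;
        double best = fromM; signed char t = 0;
        if (fromX > best) { best = fromX; t = 1; }
        if (fromY > best) { best = fromY; t = 2; }
        if (best > NEG_INF / 2) { X[k] = best; tX[k] = t; }
      }
      // Y: consume b[j-1], gap in a
      if (inBand(i, j - 1)) {
        const int kl = idx(i, j - 1);
        double fromM = (M[kl] > NEG_INF / 2) ? M[kl] - gapOpen - gapExtend
                                             : NEG_INF;
        double fromX = (X[kl] > NEG_INF / 2) ? X[kl] - gapOpen - gapExtend
                                             : NEG_INF;
        double fromY = (Y[kl] > NEG_INF / 2) ? Y[kl] - gapExtend : NEG_INF;
        double best = fromM; signed char t = 0;
        if (fromX > best) { best = fromX; t = 1; }
        if (fromY > best) { best = fromY; t = 2; }
        if (best > NEG_INF / 2) { Y[k] = best; tY[k] = t; }
      }
    }
  }

  const int kEnd = idx(n, m);
  double best = M[kEnd]; int state = 0;
  if (X[kEnd] > best) { best = X[kEnd]; state = 1; }
  if (Y[kEnd] > best) { best = Y[kEnd]; state = 2; }
  if (best < NEG_INF / 2)
    stop("band too narrow: no alignment within the band");

  // traceback
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int k = idx(i, j);
    if (state == 0) {
      signed char t = tM[k];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = t;
    } else if (state == 1) {
      signed char t = tX[k];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = t;
    } else {
      signed char t = tY[k];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = t;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = best, _["a"] = ga, _["b"] = gb);
}
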