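#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment, maximizing score.
// A gap of length L costs gap_open + L * gap_ext (BLAST convention).
// States: M (a[i] aligned to b[j]), X (gap in b, consumes a), Y (gap in a,
// consumes b).  Score rows are rolled; a full byte traceback is kept so the
// optimal alignment itself is recovered, not just its score.
//
// a, b: 1-based integer codes indexing rows/columns of sub.
// local = true  -> Smith-Waterman (M floored at 0, best cell anywhere)
// local = false -> Needleman-Wunsch (end-to-end)

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// traceback codes (predecessor state): 0 = stop, 1 = M, 2 = X, 3 = Y
// [[Rcpp::export(name = ".align_dp")]]
List align_dp(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  const double oe = gap_open + gap_ext;
  const int ncodes = sub.nrow();
  const double *subp = REAL(sub);
  const int *ap = INTEGER(a);
  const int *bp = INTEGER(b);
  for (int i = 0; i < n; ++i)
    if (ap[i] < 1 || ap[i] > ncodes)
      stop("sequence code out of range of the substitution matrix");
  for (int j = 0; j < m; ++j)
    if (bp[j] < 1 || bp[j] > ncodes)
      stop("sequence code out of range of the substitution matrix");

  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1), 0);
  unsigned char *tM = tbM.data(), *tX = tbX.data(), *tY = tbY.data();

  std::vector<double> Mbuf1(m + 1), Xbuf1(m + 1), Ybuf1(m + 1);
  std::vector<double> Mbuf2(m + 1), Xbuf2(m + 1), Ybuf2(m + 1);
  double *Mprev = Mbuf1.data(), *Xprev = Xbuf1.data(), *Yprev = Ybuf1.data();
  double *Mcur = Mbuf2.data(), *Xcur = Xbuf2.data(), *Ycur = Ybuf2.data();

  // row 0
  Mprev[0] = 0.0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = local ? 0.0 : NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = local ? NEG_INF : -(gap_open + j * gap_ext);
    if (!local) tY[(size_t)j] = (j == 1) ? 1 : 3;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0, best_state = 0;

  for (int i = 1; i <= n; ++i) {
    const double *srow = subp + (ap[i - 1] - 1);  // column-major: + col*ncodes
    unsigned char *tMr = tM + (size_t)i * (m + 1);
    unsigned char *tXr = tX + (size_t)i * (m + 1);
    unsigned char *tYr = tY + (size_t)i * (m + 1);
    Mcur[0] = local ? 0.0 : NEG_INF;
    Ycur[0] = NEG_INF;
    if (local) {
      Xcur[0] = NEG_INF;
    } else {
      Xcur[0] = -(gap_open + i * gap_ext);
      tXr[0] = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      // M state
      const double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double mv; unsigned char mt;
      if (dM >= dX && dM >= dY) { mv = dM; mt = 1; }
      else if (dX >= dY)        { mv = dX; mt = 2; }
      else                      { mv = dY; mt = 3; }
      // local: a non-positive best predecessor means the path starts here
      if (local && mv <= 0.0) mt = 0;
      mv += srow[(size_t)(bp[j - 1] - 1) * ncodes];
      if (local && mv <= 0.0) { mv = 0.0; mt = 0; }
      Mcur[j] = mv; tMr[j] = mt;

      // X state: gap in b (consume a[i])
      const double xo = Mprev[j] - oe, xx = Xprev[j] - gap_ext,
                   xy = Yprev[j] - oe;
      double xv; unsigned char xt;
      if (xo >= xx && xo >= xy) { xv = xo; xt = 1; }
      else if (xx >= xy)        { xv = xx; xt = 2; }
      else                      { xv = xy; xt = 3; }
      Xcur[j] = xv; tXr[j] = xt;

      // Y state: gap in a (consume b[j])
      const double yo = Mcur[j - 1] - oe, yy = Ycur[j - 1] - gap_ext,
                   yx = Xcur[j - 1] - oe;
      double yv; unsigned char yt;
      if (yo >= yy && yo >= yx) { yv = yo; yt = 1; }
      else if (yy >= yx)        { yv = yy; yt = 3; }
      else                      { yv = yx; yt = 2; }
      Ycur[j] = yv; tYr[j] = yt;

      if (local && mv > best) {
        best = mv; best_i = i; best_j = j; best_state = 1;
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (!local) {
    // after the final swap, *prev holds row n
    const double eM = Mprev[m], eX = Xprev[m], eY = Yprev[m];
    if (eM >= eX && eM >= eY) { best = eM; best_state = 1; }
    else if (eX >= eY)        { best = eX; best_state = 2; }
    else                      { best = eY; best_state = 3; }
    best_i = n; best_j = m;
  }

  // traceback
  std::vector<int> ar, br;
  int i = best_i, j = best_j, state = best_state;
  while (state != 0 && (i > 0 || j > 0)) {
    const size_t at = (size_t)i * (m + 1) + j;
    unsigned char prev;
    if (state == 1) {
      prev = tM[at];
      ar.push_back(i); br.push_back(j);
      --i; --j;
    } else if (state == 2) {
      prev = tX[at];
      ar.push_back(i); br.push_back(0);
      --i;
    } else {
      prev = tY[at];
      ar.push_back(0); br.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());

  return List::create(
    _["score"] = best,
    _["a_idx"] = IntegerVector(ar.begin(), ar.end()),
    _["b_idx"] = IntegerVector(br.begin(), br.end()));
}
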