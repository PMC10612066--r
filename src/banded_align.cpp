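#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global alignment with affine gaps for nucleotide strings.
// Gap of length L costs gap_open + L * gap_ext (open charged once).
// With gap_open = 0 this reduces to a linear gap penalty.
// The band must contain the main diagonal shifted by the length
// difference; callers widen and retry on band overflow.

static const double NEG = -1e18;

// state codes for traceback: which matrix the optimum came from
enum { MM = 0, XX = 1, YY = 2 };

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (band < std::abs(na - nb) + 1) band = std::abs(na - nb) + 1;
  const int W = 2 * band + 1;

  // M: a[i] aligned to b[j]; X: gap in b (consumes a); Y: gap in a.
  std::vector<double> M0(W, NEG), X0(W, NEG), Y0(W, NEG);
  std::vector<double> M1(W, NEG), X1(W, NEG), Y1(W, NEG);
  // traceback: 2 bits per matrix packed in one byte per cell
  std::vector<unsigned char> tb((size_t)(na + 1) * W, 0);

  // column index within band for row i: c = j - i + band, j in [lo, hi]
  auto colOf = [&](int i, int j) { return j - i + band; };

  // row 0
  for (int j = 0; j <= std::min(nb, band); ++j) {
    int c = colOf(0, j);
    if (j == 0) { M0[c] = 0.0; }
    else {
      Y0[c] = -(gap_open + gap_ext * j);
      tb[c] = (unsigned char)(YY << 4 | (j == 1 ? MM : YY) << 2);
    }
  }

  for (int i = 1; i <= na; ++i) {
    std::fill(M1.begin(), M1.end(), NEG);
    std::fill(X1.begin(), X1.end(), NEG);
    std::fill(Y1.begin(), Y1.end(), NEG);
    int lo = std::max(0, i - band), hi = std::min(nb, i + band);
    for (int j = lo; j <= hi; ++j) {
      int c = colOf(i, j);
      unsigned char code = 0;
      // X: gap in b, from row i-1 same j -> prev col c' = j-(i-1)+band = c+1
      if (c + 1 < W) {
        double fromM = M0[c + 1] - (gap_open + gap_ext);
        double fromX = X0[c + 1] - gap_ext;
        if (fromM >= fromX) { X1[c] = fromM; code |= MM << 0; }
        else { X1[c] = fromX; code |= XX << 0; }
      }
      // Y: gap in a, from same row j-1 -> col c-1
      if (j > lo && c - 1 >= 0) {
        double fromM = M1[c - 1] - (gap_open + gap_ext);
        double fromY = Y1[c - 1] - gap_ext;
        if (fromM >= fromY) { Y1[c] = fromM; code |= MM << 2; }
        else { Y1[c] = fromY; code |= YY << 2; }
      }
      // M: diagonal from (i-1, j-1) -> prev row col c
      if (j > 0) {
        double best = M0[c]; unsigned char st = MM;
        if (X0[c] > best) { best = X0[c]; st = XX; }
        if (Y0[c] > best) { best = Y0[c]; st = YY; }
        if (best > NEG / 2) {
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          M1[c] = best + s; code |= st << 4;
        }
      }
      tb[(size_t)i * W + c] = code;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  int cend = colOf(na, nb);
  if (cend < 0 || cend >= W)
    stop("banded alignment: end cell outside band; widen the band");
  double sM = M0[cend], sX = X0[cend], sY = Y0[cend];
  double score = sM; int state = MM;
  if (sX > score) { score = sX; state = XX; }
  if (sY > score) { score = sY; state = YY; }
  if (score < NEG / 2)
    stop("banded alignment: no path within band; widen the band");

  // traceback
  std::string ra, rb;
  ra.reserve(na + nb); rb.reserve(na + nb);
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * W + colOf(i, j)];
    if (state == MM) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      int prev = (code >> 4) & 3;
      --i; --j; state = prev;
    } else if (state == XX) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      int prev = (code >> 0) & 3;
      --i; state = prev;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      int prev = (code >> 2) & 3;
      --j; state = prev;
    }
    if (i == 0 && j > 0) state = YY;
    if (j == 0 && i > 0) state = XX;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
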