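#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact global Needleman-Wunsch with affine gaps and an arbitrary
// substitution matrix (row/column names give the alphabet).  A gap of
// length L costs gap_open + L * gap_ext.  Full dynamic-programming
// matrix; intended for protein-sized sequences.  Ties prefer the
// substitution state, then a gap in the reference, so the traceback is
// deterministic.

static const double NEG2 = -1e18;
enum { SM = 0, SX = 1, SY = 2 };

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix mat,
                  CharacterVector alphabet, double gap_open,
                  double gap_ext) {
  const int na = (int)a.size(), nb = (int)b.size();
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)CHAR(STRING_ELT(alphabet, i))[0]] = i;
  std::vector<int> ia(na), ib(nb);
  for (int i = 0; i < na; ++i) {
    ia[i] = lut[(unsigned char)a[i]];
    if (ia[i] < 0) stop("symbol not in alphabet: %c", a[i]);
  }
  for (int j = 0; j < nb; ++j) {
    ib[j] = lut[(unsigned char)b[j]];
    if (ib[j] < 0) stop("symbol not in alphabet: %c", b[j]);
  }
  const int W = nb + 1;
  std::vector<double> M((na + 1) * W, NEG2), X((na + 1) * W, NEG2),
      Y((na + 1) * W, NEG2);
  std::vector<unsigned char> tb((size_t)(na + 1) * W, 0);
  M[0] = 0.0;
  for (int j = 1; j <= nb; ++j) {
    Y[j] = -(gap_open + gap_ext * j);
    tb[j] |= (j == 1 ? SM : SY) << 2;
  }
  for (int i = 1; i <= na; ++i) {
    X[i * W] = -(gap_open + gap_ext * i);
    tb[(size_t)i * W] |= (i == 1 ? SM : SX) << 0;
    for (int j = 1; j <= nb; ++j) {
      const size_t c = (size_t)i * W + j, up = c - W, lf = c - 1,
                   dg = c - W - 1;
      unsigned char code = 0;
      // X: gap in b
      {
        double fm = M[up] - (gap_open + gap_ext), fx = X[up] - gap_ext;
        if (fm >= fx) { X[c] = fm; code |= SM << 0; }
        else { X[c] = fx; code |= SX << 0; }
      }
      // Y: gap in a
      {
        double fm = M[lf] - (gap_open + gap_ext), fy = Y[lf] - gap_ext;
        if (fm >= fy) { Y[c] = fm; code |= SM << 2; }
        else { Y[c] = fy; code |= SY << 2; }
      }
      // M: diagonal
      {
        double best = M[dg]; unsigned char st = SM;
        if (X[dg] > best) { best = X[dg]; st = SX; }
        if (Y[dg] > best) { best = Y[dg]; st = SY; }
        M[c] = best + mat(ia[i - 1], ib[j - 1]);
        code |= st << 4;
      }
      tb[c] = code;
    }
  }
  const size_t endc = (size_t)na * W + nb;
  double score = M[endc]; int state = SM;
  if (X[endc] > score) { score = X[endc]; state = SX; }
  if (Y[endc] > score) { score = Y[endc]; state = SY; }
  std::string ra, rb;
  ra.reserve(na + nb); rb.reserve(na + nb);
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * W + j];
    if (i == 0) state = SY;
    else if (j == 0) state = SX;
    if (state == SM) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = (code >> 4) & 3; --i; --j;
    } else if (state == SX) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = (code >> 0) & 3; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = (code >> 2) & 3; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
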