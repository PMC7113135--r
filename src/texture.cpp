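#include <Rcpp.h>
using namespace Rcpp;

// Uniform local binary patterns, 8 neighbors at radius 1.
// Bit i is set when neighbor_i >= center.  Patterns with at most two
// circular 0/1 transitions are "uniform"; there are 58 of them and they
// are numbered 0..57 in increasing pattern value, all others share bin 58.
// Border pixels (no full neighborhood) get code NA.
// [[Rcpp::export]]
IntegerMatrix lbp_uniform_cpp(NumericMatrix X) {
  const int H = X.nrow(), W = X.ncol();
  // lookup: pattern value -> bin
  static int lut[256];
  static bool ready = false;
  if (!ready) {
    int u = 0;
    for (int p = 0; p < 256; ++p) {
      int trans = 0;
      for (int b = 0; b < 8; ++b) {
        int b1 = (p >> b) & 1, b2 = (p >> ((b + 1) % 8)) & 1;
        if (b1 != b2) ++trans;
      }
      lut[p] = (trans <= 2) ? u++ : -1;
    }
    for (int p = 0; p < 256; ++p) if (lut[p] < 0) lut[p] = u; // 58
    ready = true;
  }
  // neighbor offsets, clockwise from east
  const int ox[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int oy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int x = 1; x < W - 1; ++x) {
    for (int y = 1; y < H - 1; ++y) {
      double c = X(y, x);
      int p = 0;
      for (int b = 0; b < 8; ++b)
        if (X(y + oy[b], x + ox[b]) >= c) p |= (1 << b);
      out(y, x) = lut[p];
    }
  }
  return out;
}

// [[Rcpp::export]]
int lbp_n_bins_cpp() { return 59; }
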