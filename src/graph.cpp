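#include <Rcpp.h>
#include <set>
#include <utility>
using namespace Rcpp;

// Unordered pairs (s, t), s < t, of distinct superpixel ids that share a
// 4-connected pixel edge.  Ids are whatever integers the map carries.
// [[Rcpp::export]]
IntegerMatrix adjacency_pairs_cpp(IntegerMatrix sp, bool diag8 = false) {
  const int H = sp.nrow(), W = sp.ncol();
  std::set<std::pair<int, int> > pairs;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int a = sp(y, x);
      if (x + 1 < W && sp(y, x + 1) != a)
        pairs.insert(std::make_pair(std::min(a, sp(y, x + 1)), std::max(a, sp(y, x + 1))));
      if (y + 1 < H && sp(y + 1, x) != a)
        pairs.insert(std::make_pair(std::min(a, sp(y + 1, x)), std::max(a, sp(y + 1, x))));
      if (diag8) {
        if (x + 1 < W && y + 1 < H && sp(y + 1, x + 1) != a)
          pairs.insert(std::make_pair(std::min(a, sp(y + 1, x + 1)), std::max(a, sp(y + 1, x + 1))));
        if (x + 1 < W && y > 0 && sp(y - 1, x + 1) != a)
          pairs.insert(std::make_pair(std::min(a, sp(y - 1, x + 1)), std::max(a, sp(y - 1, x + 1))));
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int i = 0;
  for (std::set<std::pair<int, int> >::iterator it = pairs.begin(); it != pairs.end(); ++it, ++i) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
  }
  return out;
}
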