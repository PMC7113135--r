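#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simple linear iterative clustering over (L, a, b, x, y).
// Distance: d_lab^2 + d_xy^2 * (compactness / step)^2, search window +/- step
// around each center.  Followed by connectivity enforcement: 4-connected
// components below min_size are absorbed into an adjacent segment, ids are
// re-numbered contiguously from 0.
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                       int n_segments, double compactness, int max_iter,
                       double min_size_frac) {
  const int H = L.nrow(), W = L.ncol();
  const int N = H * W;
  IntegerMatrix out(H, W);
  if (n_segments <= 1) return out;

  const double step = std::sqrt((double)N / (double)n_segments);
  // seed grid sized to yield ~n_segments centers even when step is a
  // large fraction of the image
  int ny = std::max(1, (int)std::lround(std::sqrt((double)n_segments * H / W)));
  int nx = std::max(1, (int)std::ceil((double)n_segments / ny));
  std::vector<double> cl, ca, cb, cx, cy;
  for (int gy = 0; gy < ny; ++gy) {
    for (int gx = 0; gx < nx; ++gx) {
      int iy = std::min((int)((gy + 0.5) * H / ny), H - 1);
      int ix = std::min((int)((gx + 0.5) * W / nx), W - 1);
      cl.push_back(L(iy, ix)); ca.push_back(A(iy, ix)); cb.push_back(B(iy, ix));
      cx.push_back(ix); cy.push_back(iy);
    }
  }
  const int K = (int)cl.size();
  std::vector<int> label(N, -1);
  std::vector<double> dist(N);
  const double wxy = (compactness * compactness) / (step * step);
  const int rad = (int)std::ceil(step);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int x0 = std::max(0, (int)cx[k] - rad), x1 = std::min(W - 1, (int)cx[k] + rad);
      int y0 = std::max(0, (int)cy[k] - rad), y1 = std::min(H - 1, (int)cy[k] + rad);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          double dl = L(y, x) - cl[k], da = A(y, x) - ca[k], db = B(y, x) - cb[k];
          double dxy = ((double)x - cx[k]) * ((double)x - cx[k]) +
                       ((double)y - cy[k]) * ((double)y - cy[k]);
          double d = dl * dl + da * da + db * db + dxy * wxy;
          int idx = y + H * x;
          if (d < dist[idx]) { dist[idx] = d; label[idx] = k; }
        }
      }
    }
    std::vector<double> sl(K, 0), sa(K, 0), sb(K, 0), sx(K, 0), sy(K, 0);
    std::vector<int> cnt(K, 0);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        int k = label[y + H * x];
        if (k < 0) continue;
        sl[k] += L(y, x); sa[k] += A(y, x); sb[k] += B(y, x);
        sx[k] += x; sy[k] += y; ++cnt[k];
      }
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0) {
        cl[k] = sl[k] / cnt[k]; ca[k] = sa[k] / cnt[k]; cb[k] = sb[k] / cnt[k];
        cx[k] = sx[k] / cnt[k]; cy[k] = sy[k] / cnt[k];
      }
    }
  }
  // pixels missed by every search window (possible after centers drift):
  // nearest center spatially
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int idx = y + H * x;
      if (label[idx] >= 0) continue;
      double best = R_PosInf; int bk = 0;
      for (int k = 0; k < K; ++k) {
        double d = (x - cx[k]) * (x - cx[k]) + (y - cy[k]) * (y - cy[k]);
        if (d < best) { best = d; bk = k; }
      }
      label[idx] = bk;
    }
  }

  // connectivity enforcement
  const int min_size = std::max(1, (int)(min_size_frac * step * step));
  std::vector<int> newlab(N, -1), stack;
  stack.reserve(N);
  const int dx[4] = {-1, 1, 0, 0}, dy[4] = {0, 0, -1, 1};
  int next_id = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int idx = y + H * x;
      if (newlab[idx] >= 0) continue;
      // label of an already-processed 4-neighbor, used to absorb small blobs
      int adj = -1;
      if (x > 0 && newlab[idx - H] >= 0) adj = newlab[idx - H];
      else if (y > 0 && newlab[idx - 1] >= 0) adj = newlab[idx - 1];
      stack.clear();
      stack.push_back(idx);
      newlab[idx] = next_id;
      std::vector<int> comp;
      comp.push_back(idx);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int cxp = cur / H, cyp = cur % H;
        for (int d = 0; d < 4; ++d) {
          int nx = cxp + dx[d], ny = cyp + dy[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int nidx = ny + H * nx;
          if (newlab[nidx] < 0 && label[nidx] == label[idx]) {
            newlab[nidx] = next_id;
            stack.push_back(nidx);
            comp.push_back(nidx);
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (size_t i = 0; i < comp.size(); ++i) newlab[comp[i]] = adj;
      } else {
        ++next_id;
      }
    }
  }
  // re-number contiguously (absorptions can leave gaps)
  std::vector<int> remap(next_id, -1);
  int S = 0;
  for (int i = 0; i < N; ++i) {
    int l = newlab[i];
    if (remap[l] < 0) remap[l] = S++;
  }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      out(y, x) = remap[newlab[y + H * x]];
  return out;
}
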