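// Low-level raster operations used by the detection stage:
// Canny edge extraction and 8-connected component labeling.
// Matrices are H x W, row = image v, column = image u.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export(name = ".cannyCpp")]]
IntegerMatrix cannyCpp(NumericMatrix img, double lo, double hi,
                       double sigma = 1.0) {
  int H = img.nrow(), W = img.ncol();
  if (!(lo < hi)) stop("canny thresholds must satisfy lo < hi");

  // Gaussian smoothing, border replicate
  int r = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    ks += k[t + r];
  }
  for (double &v : k) v /= ks;
  std::vector<double> tmp((size_t)H * W), sm((size_t)H * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        s += k[t + r] * img(i, jj);
      }
      tmp[(size_t)i * W + j] = s;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        s += k[t + r] * tmp[(size_t)ii * W + j];
      }
      sm[(size_t)i * W + j] = s;
    }

  // 3x3 Sobel gradients
  std::vector<double> gx((size_t)H * W, 0.0), gy((size_t)H * W, 0.0),
      mag((size_t)H * W, 0.0);
  auto at = [&](int i, int j) {
    i = std::min(std::max(i, 0), H - 1);
    j = std::min(std::max(j, 0), W - 1);
    return sm[(size_t)i * W + j];
  };
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double sx = (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
                  (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1));
      double sy = (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
                  (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1));
      size_t p = (size_t)i * W + j;
      gx[p] = sx; gy[p] = sy;
      mag[p] = std::sqrt(sx * sx + sy * sy);
    }

  // non-maximum suppression along the quantized gradient direction
  IntegerMatrix out(H, W);
  std::vector<unsigned char> strong((size_t)H * W, 0),
      weak((size_t)H * W, 0);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      size_t p = (size_t)i * W + j;
      double m = mag[p];
      if (m < lo) continue;
      double ang = std::atan2(gy[p], gx[p]) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int di1, dj1;
      if (ang < 22.5 || ang >= 157.5) { di1 = 0; dj1 = 1; }
      else if (ang < 67.5) { di1 = 1; dj1 = 1; }
      else if (ang < 112.5) { di1 = 1; dj1 = 0; }
      else { di1 = 1; dj1 = -1; }
      auto magat = [&](int ii, int jj) {
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) return 0.0;
        return mag[(size_t)ii * W + jj];
      };
      if (m >= magat(i + di1, j + dj1) && m >= magat(i - di1, j - dj1)) {
        if (m >= hi) strong[p] = 1; else weak[p] = 1;
      }
    }

  // hysteresis: keep weak edges 8-connected to a strong edge
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (strong[(size_t)i * W + j]) {
        out(i, j) = 1;
        q.push(std::make_pair(i, j));
      }
  while (!q.empty()) {
    int i = q.front().first, j = q.front().second;
    q.pop();
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        size_t p = (size_t)ii * W + jj;
        if (weak[p] && !out(ii, jj)) {
          out(ii, jj) = 1;
          q.push(std::make_pair(ii, jj));
        }
      }
  }
  return out;
}

// Binary dilation by an arbitrary 0/1 structuring element, repeated
// `iterations` times. The kernel's origin is its centre element.
// [[Rcpp::export(name = ".dilateCpp")]]
IntegerMatrix dilateCpp(IntegerMatrix mask, IntegerMatrix kernel,
                        int iterations = 1) {
  int H = mask.nrow(), W = mask.ncol();
  int kh = kernel.nrow(), kw = kernel.ncol();
  int ci = kh / 2, cj = kw / 2;
  std::vector<std::pair<int, int> > offs;
  for (int i = 0; i < kh; ++i)
    for (int j = 0; j < kw; ++j)
      if (kernel(i, j)) offs.push_back(std::make_pair(i - ci, j - cj));
  IntegerMatrix cur(clone(mask)), nxt(H, W);
  for (int it = 0; it < iterations; ++it) {
    std::fill(nxt.begin(), nxt.end(), 0);
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        if (!cur(i, j)) continue;
        for (size_t o = 0; o < offs.size(); ++o) {
          int ii = i + offs[o].first, jj = j + offs[o].second;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) nxt(ii, jj) = 1;
        }
      }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  return cur;
}

// 8-connected components of a binary mask, labeled in raster-scan
// order of their first-encountered pixel (deterministic).
// [[Rcpp::export(name = ".labelComponents8Cpp")]]
IntegerMatrix labelComponents8Cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}
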