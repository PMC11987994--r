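// Dense two-frame optical flow by local polynomial expansion
// (quadratic model per pixel, Gaussian applicability), solved
// coarse-to-fine over an image pyramid with bilinear warping and
// windowed least-squares aggregation of the displacement constraints.
//
// Images are H x W matrices, row index = image v (downward),
// column index = image u (rightward), intensities on any linear scale.
// Flow is returned as two H x W matrices: du (columns) and dv (rows),
// the displacement mapping the previous frame onto the current one.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::vector<double> Buf;

inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// separable correlation along rows (horizontal, u/x axis), border replicate
void convX(const Buf &src, Buf &dst, int H, int W, const Buf &k, int r) {
  int lo = std::min(r, W), hi = std::max(W - r, lo);
  for (int i = 0; i < H; ++i) {
    const double *row = &src[(size_t)i * W];
    double *out = &dst[(size_t)i * W];
    for (int j = 0; j < lo; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * row[clampi(j + t, 0, W - 1)];
      out[j] = s;
    }
    for (int j = lo; j < hi; ++j) {
      double s = 0.0;
      const double *p = row + j - r;
      for (int t = 0; t <= 2 * r; ++t) s += k[t] * p[t];
      out[j] = s;
    }
    for (int j = hi; j < W; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * row[clampi(j + t, 0, W - 1)];
      out[j] = s;
    }
  }
}

// separable correlation along columns (vertical, v/y axis), border replicate
void convY(const Buf &src, Buf &dst, int H, int W, const Buf &k, int r) {
  for (int i = 0; i < H; ++i) {
    double *out = &dst[(size_t)i * W];
    bool interior = (i >= r && i < H - r);
    if (interior) {
      const double *base = &src[(size_t)(i - r) * W];
      for (int j = 0; j < W; ++j) out[j] = k[0] * base[j];
      for (int t = 1; t <= 2 * r; ++t) {
        const double *p = &src[(size_t)(i - r + t) * W];
        double kt = k[t];
        for (int j = 0; j < W; ++j) out[j] += kt * p[j];
      }
    } else {
      for (int j = 0; j < W; ++j) out[j] = 0.0;
      for (int t = -r; t <= r; ++t) {
        const double *p = &src[(size_t)clampi(i + t, 0, H - 1) * W];
        double kt = k[t + r];
        for (int j = 0; j < W; ++j) out[j] += kt * p[j];
      }
    }
  }
}

Buf gaussKernel(double sigma, int r) {
  Buf k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// Quadratic polynomial expansion f(x) ~ x'Ax + b'x + c with Gaussian
// applicability. Outputs per-pixel A (a11 = x^2 coeff, a22 = y^2 coeff,
// a12 = half the xy coeff) and b = (bx, by).
struct PolyExp {
  Buf a11, a12, a22, bx, by;
};

void polyExpansion(const Buf &img, int H, int W, double sigma, int r,
                   PolyExp &out) {
  Buf g = gaussKernel(sigma, r);
  Buf gx(2 * r + 1), gxx(2 * r + 1);
  for (int t = -r; t <= r; ++t) {
    gx[t + r] = t * g[t + r];
    gxx[t + r] = (double)t * t * g[t + r];
  }
  double s0 = 0.0, s2 = 0.0, s4 = 0.0;
  for (int t = -r; t <= r; ++t) {
    s0 += g[t + r];
    s2 += t * t * g[t + r];
    s4 += (double)t * t * t * t * g[t + r];
  }
  // metric entries for the (1, x^2, y^2) block and the x, y, xy diagonals
  double a = s0 * s0, b2 = s0 * s2, c = s0 * s4, d = s2 * s2;
  // invert [[a,b2,b2],[b2,c,d],[b2,d,c]] analytically
  double det = a * (c * c - d * d) - b2 * (b2 * c - b2 * d) +
               b2 * (b2 * d - b2 * c);
  double i21 = (b2 * d - b2 * c) / det;         // row for x^2, col for 1
  double i22 = (a * c - b2 * b2) / det;         // x^2 , x^2
  double i23 = (b2 * b2 - a * d) / det;         // x^2 , y^2
  // (y^2 row is the mirror image)

  size_t n = (size_t)H * W;
  Buf t0(n), t1(n), t2(n), m1(n), mx(n), my(n), mxx(n), myy(n), mxy(n);
  convY(img, t0, H, W, g, r);
  convY(img, t1, H, W, gx, r);
  convY(img, t2, H, W, gxx, r);
  convX(t0, m1, H, W, g, r);
  convX(t0, mx, H, W, gx, r);
  convX(t0, mxx, H, W, gxx, r);
  convX(t1, my, H, W, g, r);
  convX(t1, mxy, H, W, gx, r);
  convX(t2, myy, H, W, g, r);

  out.a11.resize(n); out.a12.resize(n); out.a22.resize(n);
  out.bx.resize(n); out.by.resize(n);
  for (size_t p = 0; p < n; ++p) {
    out.bx[p] = mx[p] / b2;
    out.by[p] = my[p] / b2;
    out.a12[p] = 0.5 * (mxy[p] / d);
    out.a11[p] = i21 * m1[p] + i22 * mxx[p] + i23 * myy[p];
    out.a22[p] = i21 * m1[p] + i23 * mxx[p] + i22 * myy[p];
  }
}

double bilinear(const Buf &img, int H, int W, double x, double y) {
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  double v00 = img[(size_t)y0 * W + x0], v01 = img[(size_t)y0 * W + x1];
  double v10 = img[(size_t)y1 * W + x0], v11 = img[(size_t)y1 * W + x1];
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

void downsample2(const Buf &src, int H, int W, Buf &dst, int &H2, int &W2) {
  // 5-tap binomial smoothing then factor-2 decimation
  static const double k5[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  Buf k(k5, k5 + 5), tmp((size_t)H * W), sm((size_t)H * W);
  convX(src, tmp, H, W, k, 2);
  convY(tmp, sm, H, W, k, 2);
  H2 = (H + 1) / 2; W2 = (W + 1) / 2;
  dst.resize((size_t)H2 * W2);
  for (int i = 0; i < H2; ++i)
    for (int j = 0; j < W2; ++j)
      dst[(size_t)i * W2 + j] = sm[(size_t)std::min(2 * i, H - 1) * W +
                                   std::min(2 * j, W - 1)];
}

// One displacement refinement at a single pyramid level. The expansion of
// the (fixed) earlier frame is computed once per level and reused.
void flowStep(const PolyExp &e1, const Buf &I2, int H, int W,
              Buf &du, Buf &dv, double poly_sigma, int poly_r,
              int win_r, double win_sigma) {
  size_t n = (size_t)H * W;
  // warp current frame back by the prior flow
  Buf I2w(n);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      size_t p = (size_t)i * W + j;
      I2w[p] = bilinear(I2, H, W, j + du[p], i + dv[p]);
    }
  PolyExp e2;
  polyExpansion(I2w, H, W, poly_sigma, poly_r, e2);

  // per-pixel constraint A d = db with A = (A1+A2)/2, db = -(b2-b1)/2
  Buf m11(n), m12(n), m22(n), h1(n), h2(n);
  for (size_t p = 0; p < n; ++p) {
    double a11 = 0.5 * (e1.a11[p] + e2.a11[p]);
    double a12 = 0.5 * (e1.a12[p] + e2.a12[p]);
    double a22 = 0.5 * (e1.a22[p] + e2.a22[p]);
    double dbx = -0.5 * (e2.bx[p] - e1.bx[p]);
    double dby = -0.5 * (e2.by[p] - e1.by[p]);
    m11[p] = a11 * a11 + a12 * a12;
    m12[p] = a11 * a12 + a12 * a22;
    m22[p] = a12 * a12 + a22 * a22;
    h1[p] = a11 * dbx + a12 * dby;
    h2[p] = a12 * dbx + a22 * dby;
  }
  // aggregate the normal equations over a Gaussian window
  Buf g = gaussKernel(win_sigma, win_r), tmp(n);
  Buf *fields[5] = {&m11, &m12, &m22, &h1, &h2};
  for (Buf *f : fields) {
    convX(*f, tmp, H, W, g, win_r);
    convY(tmp, *f, H, W, g, win_r);
  }
  const double eps = 1e-6;
  for (size_t p = 0; p < n; ++p) {
    double det = (m11[p] + eps) * (m22[p] + eps) - m12[p] * m12[p];
    double ddu = ((m22[p] + eps) * h1[p] - m12[p] * h2[p]) / det;
    double ddv = ((m11[p] + eps) * h2[p] - m12[p] * h1[p]) / det;
    du[p] += ddu;
    dv[p] += ddv;
  }
}

} // namespace

// [[Rcpp::export(name = ".denseFlowCpp")]]
List denseFlowCpp(NumericMatrix prev, NumericMatrix cur,
                  int levels = 4, int iters = 2,
                  double poly_sigma = 1.5, int poly_radius = 3,
                  int win_radius = 6) {
  int H = prev.nrow(), W = prev.ncol();
  if (cur.nrow() != H || cur.ncol() != W)
    stop("frame dimensions differ");
  double win_sigma = win_radius / 2.0;

  // build pyramids (level 0 = full resolution)
  std::vector<Buf> p1(1), p2(1);
  std::vector<int> hs(1, H), ws(1, W);
  p1[0].resize((size_t)H * W);
  p2[0].resize((size_t)H * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      p1[0][(size_t)i * W + j] = prev(i, j);
      p2[0][(size_t)i * W + j] = cur(i, j);
    }
  int minside = 4 * poly_radius + 4;
  for (int l = 1; l < levels; ++l) {
    int h0 = hs[l - 1], w0 = ws[l - 1];
    if (h0 / 2 < minside || w0 / 2 < minside) break;
    Buf d1, d2; int h2, w2;
    downsample2(p1[l - 1], h0, w0, d1, h2, w2);
    downsample2(p2[l - 1], h0, w0, d2, h2, w2);
    p1.push_back(d1); p2.push_back(d2);
    hs.push_back(h2); ws.push_back(w2);
  }

  int top = (int)p1.size() - 1;
  Buf du((size_t)hs[top] * ws[top], 0.0), dv(du);
  for (int l = top; l >= 0; --l) {
    int h = hs[l], w = ws[l];
    if (l < top) {
      // upsample the flow from the coarser level and double it
      int hc = hs[l + 1], wc = ws[l + 1];
      Buf du2((size_t)h * w), dv2((size_t)h * w);
      for (int i = 0; i < h; ++i)
        for (int j = 0; j < w; ++j) {
          double x = j * (wc - 1.0) / std::max(w - 1, 1);
          double y = i * (hc - 1.0) / std::max(h - 1, 1);
          du2[(size_t)i * w + j] = 2.0 * bilinear(du, hc, wc, x, y);
          dv2[(size_t)i * w + j] = 2.0 * bilinear(dv, hc, wc, x, y);
        }
      du.swap(du2); dv.swap(dv2);
    }
    PolyExp e1;
    polyExpansion(p1[l], h, w, poly_sigma, poly_radius, e1);
    for (int it = 0; it < iters; ++it)
      flowStep(e1, p2[l], h, w, du, dv, poly_sigma, poly_radius,
               win_radius, win_sigma);
  }

  NumericMatrix duM(H, W), dvM(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      duM(i, j) = du[(size_t)i * W + j];
      dvM(i, j) = dv[(size_t)i * W + j];
    }
  return List::create(_["du"] = duM, _["dv"] = dvM);
}
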