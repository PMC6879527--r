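// Minimal CNN kernels for the U-shaped segmenters and tooth classifiers.
// Layout conventions (column-major, matching R arrays):
//   feature maps: H x W x C
//   conv weights: kh x kw x Cin x Cout, "same" zero padding, stride 1
#include <Rcpp.h>
using namespace Rcpp;

static inline int at3(int h, int w, int c, int H, int W) {
  return h + H * (w + W * c);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wgt, NumericVector b,
                            IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y(H * W * Cout);
  const double *px = x.begin(), *pw_ = wgt.begin();
  double *py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        py[at3(h, w, co, H, W)] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const double wv = pw_[i + kh * (j + kw * (ci + Cin * co))];
          if (wv == 0.0) continue;
          const int dh = i - ph, dw = j - pw;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int w = w0; w < w1; ++w) {
            const double *xcol = px + at3(0, w + dw, ci, H, W) + dh;
            double *ycol = py + at3(0, w, co, H, W);
            for (int h = h0; h < h1; ++h) ycol[h] += wv * xcol[h];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector wgt, NumericVector gy,
                   IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx(x.size()), gw(wgt.size()), gb(Cout);
  const double *px = x.begin(), *pw_ = wgt.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    double bsum = 0.0;
    const double *gcol0 = pgy + at3(0, 0, co, H, W);
    for (int k = 0; k < H * W; ++k) bsum += gcol0[k];
    gb[co] = bsum;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int widx = i + kh * (j + kw * (ci + Cin * co));
          const double wv = pw_[widx];
          const int dh = i - ph, dw = j - pw;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          double wsum = 0.0;
          for (int w = w0; w < w1; ++w) {
            const double *xcol = px + at3(0, w + dw, ci, H, W) + dh;
            double *gxcol = pgx + at3(0, w + dw, ci, H, W) + dh;
            const double *gycol = pgy + at3(0, w, co, H, W);
            for (int h = h0; h < h1; ++h) {
              wsum += xcol[h] * gycol[h];
              gxcol[h] += wv * gycol[h];
            }
          }
          pgw[widx] += wsum;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled map and
// 1-based argmax indices into the input (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        int best = at3(2 * h, 2 * w, c, H, W);
        double bv = px[best];
        const int cand[3] = {at3(2 * h + 1, 2 * w, c, H, W),
                             at3(2 * h, 2 * w + 1, c, H, W),
                             at3(2 * h + 1, 2 * w + 1, c, H, W)};
        for (int k = 0; k < 3; ++k)
          if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
        const int o = at3(h, w, c, Ho, Wo);
        y[o] = bv;
        idx[o] = best + 1;
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx(xdim[0] * xdim[1] * xdim[2]);
  for (int k = 0; k < gy.size(); ++k) gx[idx[k] - 1] += gy[k];
  gx.attr("dim") = xdim;
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint (sum over 2x2 blocks).
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector y(4 * H * W * C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = px[at3(h, w, c, H, W)];
        py[at3(2 * h,     2 * w,     c, 2 * H, 2 * W)] = v;
        py[at3(2 * h + 1, 2 * w,     c, 2 * H, 2 * W)] = v;
        py[at3(2 * h,     2 * w + 1, c, 2 * H, 2 * W)] = v;
        py[at3(2 * h + 1, 2 * w + 1, c, 2 * H, 2 * W)] = v;
      }
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy, IntegerVector ydim) {
  const int H2 = ydim[0], W2 = ydim[1], C = ydim[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(H * W * C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        px[at3(h, w, c, H, W)] =
          pg[at3(2 * h,     2 * w,     c, H2, W2)] +
          pg[at3(2 * h + 1, 2 * w,     c, H2, W2)] +
          pg[at3(2 * h,     2 * w + 1, c, H2, W2)] +
          pg[at3(2 * h + 1, 2 * w + 1, c, H2, W2)];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
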