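// Low-level image/tensor kernels backing the autodiff engine.
// Tensors are R arrays with dim c(H, W, C), column-major.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Unfold an (H,W,C) tensor into a (kh*kw*C) x (Ho*Wo) patch matrix
// (zero padding). Column j corresponds to output pixel (j %% Ho, j / Ho).
// [[Rcpp::export]]
NumericMatrix vs_im2col(NumericVector x, int H, int W, int C,
                        int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = op + (size_t)(ho + wo * Ho) * K;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int wj = w0 + j;
          const bool win = (wj >= 0 && wj < W);
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            col[i + j * kh + c * kh * kw] =
              (win && hi >= 0 && hi < H) ? xc[hi + (size_t)wj * H] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of vs_im2col: fold a patch matrix back into an (H,W,C) tensor,
// accumulating overlapping contributions.
// [[Rcpp::export]]
NumericVector vs_col2im(NumericMatrix cols, int H, int W, int C,
                        int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x(H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = cp + (size_t)(ho + wo * Ho) * K;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int wj = w0 + j;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)wj * H] += col[i + j * kh + c * kh * kw];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Depthwise 'valid' cross-correlation of an (H,W,C) tensor with one 2-D
// kernel applied to every channel (used by the windowed SSIM statistics).
// [[Rcpp::export]]
NumericVector vs_dwcorr_valid(NumericVector x, int H, int W, int C,
                              NumericMatrix k) {
  const int kh = k.nrow(), kw = k.ncol();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericVector y(Ho * Wo * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* yc = yp + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0;
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i)
            s += k(i, j) * xc[(ho + i) + (size_t)(wo + j) * H];
        yc[ho + (size_t)wo * Ho] = s;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// Adjoint of vs_dwcorr_valid: scatter a (Ho,Wo,C) gradient back to (H,W,C).
// [[Rcpp::export]]
NumericVector vs_dwcorr_valid_bw(NumericVector g, int H, int W, int C,
                                 NumericMatrix k) {
  const int kh = k.nrow(), kw = k.ncol();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericVector x(H * W * C);
  const double* gp = g.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + (size_t)c * Ho * Wo;
    double* xc = xp + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double gv = gc[ho + (size_t)wo * Ho];
        if (gv == 0.0) continue;
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i)
            xc[(ho + i) + (size_t)(wo + j) * H] += gv * k(i, j);
      }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Nearest-neighbour 2x upsampling of (H,W,C).
// [[Rcpp::export]]
NumericVector vs_upsample2(NumericVector x, int H, int W, int C) {
  NumericVector y(4 * H * W * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const int H2 = 2 * H;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* yc = yp + (size_t)c * H2 * 2 * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xc[h + (size_t)w * H];
        const size_t b = (size_t)(2 * h) + (size_t)(2 * w) * H2;
        yc[b] = v; yc[b + 1] = v; yc[b + H2] = v; yc[b + H2 + 1] = v;
      }
  }
  y.attr("dim") = IntegerVector::create(H2, 2 * W, C);
  return y;
}

// Adjoint of vs_upsample2: 2x2 block-sum pooling.
// [[Rcpp::export]]
NumericVector vs_downsum2(NumericVector g, int H2, int W2, int C) {
  const int H = H2 / 2, W = W2 / 2;
  NumericVector x(H * W * C);
  const double* gp = g.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + (size_t)c * H2 * W2;
    double* xc = xp + (size_t)c * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t b = (size_t)(2 * h) + (size_t)(2 * w) * H2;
        xc[h + (size_t)w * H] = gc[b] + gc[b + 1] + gc[b + H2] + gc[b + H2 + 1];
      }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
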