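#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, B, C), column-major. im2col unrolls
// the zero-padded 3x3 neighbourhood of every pixel of every batch image into
// a (H*W*B) x (9*C) matrix so that a same-padding 3x3 convolution becomes a
// single matrix product with a (9*C) x C_out kernel matrix. Row index is
// h + H*w + H*W*b; column index is k + 9*c with k = (dh+1) + 3*(dw+1).

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int H, int W, int B, int C) {
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t N = plane * B;
  NumericMatrix out(N, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    for (int k = 0; k < 9; ++k) {
      const int dh = k % 3 - 1, dw = k / 3 - 1;
      double* o = &out(0, k + 9 * c);
      const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      for (int b = 0; b < B; ++b) {
        const double* xb = xc + plane * b;
        double* ob = o + plane * b;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;  // zero padding
          const double* xw = xb + (R_xlen_t)H * ws;
          double* ow = ob + (R_xlen_t)H * w;
          std::copy(xw + h0 + dh, xw + h1 + dh, ow + h0);
        }
      }
    }
  }
  return out;
}

// In-place column-wise bias add on a freshly allocated gemm result (the
// caller guarantees the matrix is not shared).

// [[Rcpp::export]]
void add_bias_ip(NumericMatrix z, NumericVector b) {
  const int nr = z.nrow(), nc = z.ncol();
  for (int j = 0; j < nc; ++j) {
    double* col = &z(0, j);
    const double bj = b[j];
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// 2x2 stride-2 max pooling on a (H, W, B, C) tensor (H, W even). Returns the
// pooled tensor plus the 1-based argmax quadrant per output cell, which
// pool2_bwd uses to route gradients.

// [[Rcpp::export]]
List pool2_fwd(NumericVector x, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t N = (R_xlen_t)Ho * Wo * B * C;
  NumericVector y(N);
  IntegerVector amax(N);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int bc = 0; bc < B * C; ++bc) {
    const double* plane = xp + (R_xlen_t)H * W * bc;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = plane + (R_xlen_t)H * (2 * wo);
      const double* c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho, ++o) {
        const int h = 2 * ho;
        double best = c0[h]; int arg = 1;
        if (c0[h + 1] > best) { best = c0[h + 1]; arg = 2; }
        if (c1[h] > best) { best = c1[h]; arg = 3; }
        if (c1[h + 1] > best) { best = c1[h + 1]; arg = 4; }
        y[o] = best; amax[o] = arg;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector pool2_bwd(NumericVector dy, IntegerVector amax, int H, int W,
                        int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * B * C);
  double* dxp = dx.begin();
  R_xlen_t o = 0;
  for (int bc = 0; bc < B * C; ++bc) {
    double* plane = dxp + (R_xlen_t)H * W * bc;
    for (int wo = 0; wo < Wo; ++wo) {
      double* c0 = plane + (R_xlen_t)H * (2 * wo);
      double* c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho, ++o) {
        const int h = 2 * ho;
        switch (amax[o]) {
          case 1: c0[h] += dy[o]; break;
          case 2: c0[h + 1] += dy[o]; break;
          case 3: c1[h] += dy[o]; break;
          default: c1[h + 1] += dy[o];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// Adjoint of im2col3: scatter-accumulate a (H*W*B) x (9*C) gradient matrix
// back onto the (H, W, B, C) input tensor.

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix cols, int H, int W, int B, int C) {
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t N = plane * B;
  NumericVector out(N * C);
  for (int c = 0; c < C; ++c) {
    double* xc = out.begin() + N * c;
    for (int k = 0; k < 9; ++k) {
      const int dh = k % 3 - 1, dw = k / 3 - 1;
      const double* g = &cols(0, k + 9 * c);
      const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      for (int b = 0; b < B; ++b) {
        double* xb = xc + plane * b;
        const double* gb = g + plane * b;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          double* xw = xb + (R_xlen_t)H * ws;
          const double* gw = gb + (R_xlen_t)H * w;
          for (int h = h0; h < h1; ++h) xw[h + dh] += gw[h];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, B, C);
  return out;
}
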