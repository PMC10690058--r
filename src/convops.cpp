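#include <Rcpp.h>
using namespace Rcpp;

// Gather/scatter kernels for the 3x3 same-padded convolution and 2x2
// ceil-mode max pooling used by the network engine. Activations are stored
// as (H, W, C, B) column-major arrays; patch matrices have one row per
// output pixel in (h, w, b) order and one column per (kernel offset, input
// channel) with the offset index fastest, so that the weight matrix is the
// plain column-major flattening of a (3, 3, Cin, Cout) kernel array.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector a, int H, int W, int C, int B) {
  const int HW = H * W;
  const int rows = HW * B;
  NumericMatrix P(rows, 9 * C);
  const double *x = a.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        // offset index in column-major (kh, kw) order within the 3x3 kernel
        int k = (kw + 1) * 3 + (kh + 1);
        double *col = &P(0, c * 9 + k);
        for (int b = 0; b < B; ++b) {
          const double *xb = x + (size_t)(b * C + c) * HW;
          double *cb = col + (size_t)b * HW;
          for (int w = 0; w < W; ++w) {
            int sw = w + kw;
            if (sw < 0 || sw >= W) continue;  // zero padding
            int h0 = (kh < 0) ? 1 : 0;
            int h1 = (kh > 0) ? H - 1 : H;
            const double *src = xb + (size_t)sw * H + kh;
            double *dst = cb + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] = src[h];
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix P, int H, int W, int C, int B) {
  const int HW = H * W;
  NumericVector out((R_xlen_t)H * W * C * B);
  out.attr("dim") = IntegerVector::create(H, W, C, B);
  double *x = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        int k = (kw + 1) * 3 + (kh + 1);
        const double *col = &P(0, c * 9 + k);
        for (int b = 0; b < B; ++b) {
          double *xb = x + (size_t)(b * C + c) * HW;
          const double *cb = col + (size_t)b * HW;
          for (int w = 0; w < W; ++w) {
            int sw = w + kw;
            if (sw < 0 || sw >= W) continue;
            int h0 = (kh < 0) ? 1 : 0;
            int h1 = (kh > 0) ? H - 1 : H;
            double *dst = xb + (size_t)sw * H + kh;
            const double *src = cb + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector a, int H, int W, int C, int B) {
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  const int n = Ho * Wo * C * B;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector arg(n);  // linear index into the input of each maximum
  const double *x = a.begin();
  double *y = out.begin();
  size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double *xc = x + (size_t)(b * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          int h = 2 * ho, w = 2 * wo;
          double best = xc[(size_t)w * H + h];
          int besti = w * H + h;
          if (h + 1 < H) {
            double v = xc[(size_t)w * H + h + 1];
            if (v > best) { best = v; besti = w * H + h + 1; }
          }
          if (w + 1 < W) {
            double v = xc[(size_t)(w + 1) * H + h];
            if (v > best) { best = v; besti = (w + 1) * H + h; }
            if (h + 1 < H) {
              v = xc[(size_t)(w + 1) * H + h + 1];
              if (v > best) { best = v; besti = (w + 1) * H + h + 1; }
            }
          }
          y[o] = best;
          arg[o] = (b * C + c) * H * W + besti;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector argmax,
                                    int H, int W, int C, int B) {
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  double *d = dx.begin();
  const double *g = dy.begin();
  for (R_xlen_t i = 0; i < argmax.size(); ++i) d[argmax[i]] += g[i];
  return dx;
}
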