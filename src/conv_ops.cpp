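// Patch-matrix (im2col) construction and its transpose scatter (col2im) for
// the 3x3 same-padding convolutions of the CNN engine. Activations are laid
// out (H, W, B, C) column-major; the patch matrix has one row per output
// pixel (pixel-major, batch outermost) and one column per (offset, channel)
// with the offset block-major, matching the weight-matrix row order used on
// the R side.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector X, int H, int W, int B, int C, int k) {
  const int pad = (k - 1) / 2;
  const size_t n = (size_t)H * W * B;
  NumericMatrix M(n, (size_t)k * k * C);
  const double *xp = REAL(X);
  double *mp = REAL(M);
  for (int dc = 0; dc < k; ++dc) {
    for (int dr = 0; dr < k; ++dr) {
      const int blk = dc * k + dr;
      const int r0 = std::max(0, pad - dr);       // first valid output row
      const int r1 = std::min(H, H + pad - dr);   // one past last valid row
      for (int c = 0; c < C; ++c) {
        double *col = mp + n * (size_t)(blk * C + c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dc - pad;
            if (ws < 0 || ws >= W) continue;      // zero padding
            const size_t outbase = (size_t)H * (w + (size_t)W * b);
            const size_t inbase =
              (size_t)H * (ws + (size_t)W * (b + (size_t)B * c));
            const double *src = xp + inbase + r0 + dr - pad;
            std::copy(src, src + (r1 - r0), col + outbase + r0);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix M, int H, int W, int B, int C, int k) {
  const int pad = (k - 1) / 2;
  const size_t n = (size_t)H * W * B;
  NumericVector out((size_t)H * W * B * C);   // zero-initialized
  double *op = REAL(out);
  const double *mp = REAL(M);
  for (int dc = 0; dc < k; ++dc) {
    for (int dr = 0; dr < k; ++dr) {
      const int blk = dc * k + dr;
      const int r0 = std::max(0, pad - dr);
      const int r1 = std::min(H, H + pad - dr);
      for (int c = 0; c < C; ++c) {
        const double *col = mp + n * (size_t)(blk * C + c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dc - pad;
            if (ws < 0 || ws >= W) continue;
            const size_t outbase = (size_t)H * (w + (size_t)W * b);
            const size_t inbase =
              (size_t)H * (ws + (size_t)W * (b + (size_t)B * c));
            double *dst = op + inbase + r0 + dr - pad;
            const double *src = col + outbase + r0;
            for (int h = 0; h < r1 - r0; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, B, C);
  return out;
}
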