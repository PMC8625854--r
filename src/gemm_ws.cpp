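// In-place helpers so the big im2col patch matrices are allocated once per
// training run and reused across batches: filling a preallocated M,
// multiplying into a preallocated result through the BLAS dgemm R links,
// and adding a per-column bias in place.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// [[Rcpp::export]]
void im2col_into(NumericVector X, NumericMatrix M, int H, int W, int B,
                 int C, int k) {
  const int pad = (k - 1) / 2;
  const size_t n = (size_t)H * W * B;
  if ((size_t)M.nrow() != n || M.ncol() != k * k * C)
    stop("workspace matrix has the wrong shape");
  const double *xp = REAL(X);
  double *mp = REAL(M);
  for (int dc = 0; dc < k; ++dc) {
    for (int dr = 0; dr < k; ++dr) {
      const int blk = dc * k + dr;
      const int r0 = std::max(0, pad - dr);
      const int r1 = std::min(H, H + pad - dr);
      for (int c = 0; c < C; ++c) {
        double *col = mp + n * (size_t)(blk * C + c);
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int ws = w + dc - pad;
            double *dst = col + (size_t)H * (w + (size_t)W * b);
            if (ws < 0 || ws >= W) { std::fill(dst, dst + H, 0.0); continue; }
            if (r0 > 0) std::fill(dst, dst + r0, 0.0);
            if (r1 < H) std::fill(dst + r1, dst + H, 0.0);
            const size_t inbase =
              (size_t)H * (ws + (size_t)W * (b + (size_t)B * c));
            const double *src = xp + inbase + r0 + dr - pad;
            std::copy(src, src + (r1 - r0), dst + r0);
          }
        }
      }
    }
  }
}

// C = A %*% t(B), written into preallocated C
// [[Rcpp::export]]
void gemm_nt_into(NumericMatrix A, NumericMatrix Bm, NumericMatrix C) {
  const int m = A.nrow(), k = A.ncol(), n = Bm.nrow();
  if (Bm.ncol() != k || C.nrow() != m || C.ncol() != n)
    stop("gemm_nt_into: incompatible shapes");
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, REAL(A), &m, REAL(Bm), &n,
                  &zero, REAL(C), &m FCONE FCONE);
}

// y[, j] += b[j] in place, treating y as an (len/ncol) x ncol matrix
// whatever its dim attribute says (so 4-D activation arrays work directly)
// [[Rcpp::export]]
void add_bias_cols(NumericVector Y, NumericVector b) {
  const int ncol = b.size();
  const size_t n = Y.size() / ncol;
  double *yp = REAL(Y);
  for (int j = 0; j < ncol; ++j) {
    const double bj = b[j];
    double *col = yp + n * (size_t)j;
    for (size_t i = 0; i < n; ++i) col[i] += bj;
  }
}
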