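// Fused elementwise/normalization layers: single-pass C++ versions of the
// ReLU/sigmoid activations, spatial batch normalization and 2x2 max
// pooling, which in plain R cost several large temporary allocations each
// per batch.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector X) {
  NumericVector Y(X.size());
  const double *xp = REAL(X); double *yp = REAL(Y);
  const size_t n = X.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// dY *= (Y > 0), in place (dY is always a fresh gradient buffer)
// [[Rcpp::export]]
void relu_bwd_ip(NumericVector dY, NumericVector Y) {
  double *dp = REAL(dY); const double *yp = REAL(Y);
  const size_t n = dY.size();
  for (size_t i = 0; i < n; ++i) if (yp[i] <= 0) dp[i] = 0.0;
}

// [[Rcpp::export]]
NumericVector sigmoid_fwd(NumericVector X) {
  NumericVector Y(X.size());
  const double *xp = REAL(X); double *yp = REAL(Y);
  const size_t n = X.size();
  for (size_t i = 0; i < n; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// dY *= Y * (1 - Y), in place
// [[Rcpp::export]]
void sigmoid_bwd_ip(NumericVector dY, NumericVector Y) {
  double *dp = REAL(dY); const double *yp = REAL(Y);
  const size_t n = dY.size();
  for (size_t i = 0; i < n; ++i) dp[i] *= yp[i] * (1.0 - yp[i]);
}

// Spatial batchnorm forward over an (n x C)-shaped activation (n = H*W*B).
// Returns y, xhat, mu, var. In inference mode mu/var are the running stats.
// [[Rcpp::export]]
List bn_fwd(NumericVector X, int C, NumericVector gamma, NumericVector beta,
            NumericVector mu, NumericVector var, bool useGiven, double eps) {
  const size_t n = X.size() / C;
  NumericVector Y(X.size()), XH(X.size());
  NumericVector muOut(C), varOut(C);
  const double *xp = REAL(X);
  double *yp = REAL(Y), *hp = REAL(XH);
  for (int c = 0; c < C; ++c) {
    const double *x = xp + n * (size_t)c;
    double m, v;
    if (useGiven) {
      m = mu[c]; v = var[c];
    } else {
      double s = 0, s2 = 0;
      for (size_t i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      m = s / n; v = s2 / n - m * m;
      if (v < 0) v = 0;
    }
    muOut[c] = m; varOut[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double *y = yp + n * (size_t)c, *h = hp + n * (size_t)c;
    for (size_t i = 0; i < n; ++i) {
      h[i] = (x[i] - m) * inv;
      y[i] = g * h[i] + b;
    }
  }
  Y.attr("dim") = X.attr("dim");
  return List::create(Named("y") = Y, Named("xhat") = XH,
                      Named("mu") = muOut, Named("var") = varOut);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dY, NumericVector XH, int C, NumericVector gamma,
            NumericVector var, double eps) {
  const size_t n = dY.size() / C;
  NumericVector dX(dY.size()), dgamma(C), dbeta(C);
  const double *dp = REAL(dY), *hp = REAL(XH);
  double *op = REAL(dX);
  for (int c = 0; c < C; ++c) {
    const double *dy = dp + n * (size_t)c, *h = hp + n * (size_t)c;
    double sdy = 0, sdyh = 0;
    for (size_t i = 0; i < n; ++i) { sdy += dy[i]; sdyh += dy[i] * h[i]; }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c];
    double *dx = op + n * (size_t)c;
    const double a = g * inv / n;
    for (size_t i = 0; i < n; ++i)
      dx[i] = a * (n * dy[i] - sdy - h[i] * sdyh);
  }
  dX.attr("dim") = dY.attr("dim");
  return List::create(Named("dX") = dX, Named("gamma") = dgamma,
                      Named("beta") = dbeta);
}

// 2x2 max pooling on (H, W, B, C); returns pooled values and the argmax
// quadrant (0..3, first maximum wins) for the backward pass.
// [[Rcpp::export]]
List pool_fwd(NumericVector X, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t npl = (size_t)B * C;
  NumericVector Y((size_t)Ho * Wo * npl);
  IntegerVector A((size_t)Ho * Wo * npl);
  const double *xp = REAL(X);
  double *yp = REAL(Y); int *ap = INTEGER(A);
  for (size_t pc = 0; pc < npl; ++pc) {
    const double *x = xp + (size_t)H * W * pc;
    double *y = yp + (size_t)Ho * Wo * pc;
    int *a = ap + (size_t)Ho * Wo * pc;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const size_t i11 = (size_t)(2 * h) + (size_t)H * (2 * w);
        // quadrant order: same-row/same-col first (row-major tie-breaking)
        const double v[4] = {x[i11], x[i11 + H],
                             x[i11 + 1], x[i11 + H + 1]};
        int best = 0;
        for (int q = 1; q < 4; ++q) if (v[q] > v[best]) best = q;
        y[h + (size_t)Ho * w] = v[best];
        a[h + (size_t)Ho * w] = best;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(Named("y") = Y, Named("arg") = A);
}

// [[Rcpp::export]]
NumericVector pool_bwd(NumericVector dY, IntegerVector A, int H, int W,
                       int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t npl = (size_t)B * C;
  NumericVector dX((size_t)H * W * npl);   // zero-initialized
  const double *dp = REAL(dY); const int *ap = INTEGER(A);
  double *op = REAL(dX);
  for (size_t pc = 0; pc < npl; ++pc) {
    const double *dy = dp + (size_t)Ho * Wo * pc;
    const int *a = ap + (size_t)Ho * Wo * pc;
    double *dx = op + (size_t)H * W * pc;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int q = a[h + (size_t)Ho * w];
        const size_t i11 = (size_t)(2 * h) + (size_t)H * (2 * w);
        const size_t off = ((q == 1 || q == 3) ? (size_t)H : 0) +
                           ((q == 2 || q == 3) ? 1 : 0);
        dx[i11 + off] = dy[h + (size_t)Ho * w];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, B, C);
  return dX;
}
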