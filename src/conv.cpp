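// Batched 2-D convolution (cross-correlation convention, zero same-padding)
// as direct shift-accumulate loops — the double-precision reference path.
// For the small kernel counts used here this is memory-friendlier than
// im2col + gemm: each input plane stays cache-resident while all kernel
// taps sweep it. Layouts are R column-major arrays:
//   x  : (H, W, Cin, N)    feature maps
//   w  : (s, s, Cin, Cout) kernels
//   y  : (H, W, Cout, N)

#include <Rcpp.h>
#include <cstring>
#include "kernels.h"

using namespace Rcpp;

static void get_dims4(const NumericVector& a, int d[4], const char* name) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("'%s' must be a 4-d array", name);
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, bool relu = false) {
  int dx[4], dw[4];
  get_dims4(x, dx, "x");
  get_dims4(w, dw, "w");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int s = dw[0], Cout = dw[3];
  if (dw[1] != s) stop("kernels must be square");
  if (s % 2 == 0) stop("kernel size must be odd");
  if (dw[2] != Cin) stop("kernel input channels (%d) != x channels (%d)",
                         dw[2], Cin);
  if (b.size() != Cout) stop("bias length != kernel count");
  const size_t HW = (size_t)H * W;

  NumericVector y((R_xlen_t)(HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    conv_sample_fwd(REAL(x) + (size_t)n * Cin * HW,
                    REAL(y) + (size_t)n * Cout * HW, REAL(w), REAL(b), H, W,
                    Cin, Cout, s, relu);
  }
  return y;
}

// Gradients of the same-padded convolution. gy must already include any
// activation masking. Returns gx, gw, gb.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx, "x");
  get_dims4(w, dw, "w");
  get_dims4(gy, dg, "gy");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int s = dw[0], Cout = dw[3];
  if (dg[0] != H || dg[1] != W || dg[2] != Cout || dg[3] != N)
    stop("gradient shape does not match forward output");
  const size_t HW = (size_t)H * W;

  NumericVector gx((R_xlen_t)(HW * Cin * N));
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw((R_xlen_t)s * s * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(s, s, Cin, Cout);
  NumericVector gb(Cout);
  std::memset(REAL(gx), 0, sizeof(double) * gx.size());
  std::memset(REAL(gw), 0, sizeof(double) * gw.size());

  for (int n = 0; n < N; ++n) {
    conv_sample_bwd(REAL(x) + (size_t)n * Cin * HW, REAL(w),
                    REAL(gy) + (size_t)n * Cout * HW,
                    REAL(gx) + (size_t)n * Cin * HW, REAL(gw), REAL(gb), H,
                    W, Cin, Cout, s);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Valid-mode 2-D correlation of a single-channel image with a small kernel
// (used for SSIM local statistics). Output is (H-kh+1) x (W-kw+1).
// [[Rcpp::export]]
NumericMatrix cpp_filter2_valid(NumericMatrix x, NumericMatrix k) {
  const int H = x.nrow(), W = x.ncol(), kh = k.nrow(), kw = k.ncol();
  if (kh > H || kw > W) stop("kernel larger than image");
  const int oh = H - kh + 1, ow = W - kw + 1;
  NumericMatrix y(oh, ow);
  for (int c = 0; c < ow; ++c)
    for (int r = 0; r < oh; ++r) {
      double acc = 0.0;
      for (int dc = 0; dc < kw; ++dc)
        for (int dr = 0; dr < kh; ++dr)
          acc += x(r + dr, c + dc) * k(dr, dc);
      y(r, c) = acc;
    }
  return y;
}
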