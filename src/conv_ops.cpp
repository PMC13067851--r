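#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensor layout convention for all ops here: channels-first column-major,
// i.e. an array [C, H, W, B] stored with C fastest. Patch rows in the
// unfolded matrix are ordered c fastest, then kh, then kw, matching weight
// matrices of shape [C_out, C*k*k].

static void im2col_fill(double *op, const double *xp, int C, int H, int W,
                        int B, int k, int pad, int stride, int Ho, int Wo);

// Unfold x [C,H,W,B] into a matrix [C*k*k, Ho*Wo*B] for a k x k kernel with
// the given zero padding and stride.
// [[Rcpp::export]]
NumericMatrix im2col_cf(NumericVector x, int C, int H, int W, int B,
                        int k, int pad, int stride, int Ho, int Wo) {
  NumericMatrix out(C * k * k, Ho * Wo * B);
  im2col_fill(out.begin(), x.begin(), C, H, W, B, k, pad, stride, Ho, Wo);
  return out;
}

// In-place variant writing into a preallocated column matrix (reused across
// minibatches to avoid large transient allocations). Fully overwrites cols.
// [[Rcpp::export]]
void im2col_into(NumericMatrix cols, NumericVector x, int C, int H, int W,
                 int B, int k, int pad, int stride, int Ho, int Wo) {
  if (cols.nrow() != C * k * k || cols.ncol() != Ho * Wo * B)
    stop("im2col buffer has wrong shape");
  im2col_fill(cols.begin(), x.begin(), C, H, W, B, k, pad, stride, Ho, Wo);
}

static void im2col_fill(double *op, const double *xp, int C, int H, int W,
                        int B, int k, int pad, int stride, int Ho, int Wo) {
  const int rows = C * k * k;
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (R_xlen_t)b * C * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double *col = op + (R_xlen_t)rows * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (iw < 0 || iw >= W || ih < 0 || ih >= H) {
              std::memset(col + r, 0, C * sizeof(double)); r += C;
            } else {
              std::memcpy(col + r, xb + (R_xlen_t)C * (iw * H + ih),
                          C * sizeof(double));
              r += C;
            }
          }
        }
      }
    }
  }
}

// Fold (scatter-add) a column matrix back to an array [C,H,W,B]; adjoint of
// im2col and also the forward map of a stride-s transposed convolution.
// [[Rcpp::export]]
NumericVector col2im_cf(NumericMatrix cols, int C, int H, int W, int B,
                        int k, int pad, int stride, int Ho, int Wo) {
  NumericVector x((R_xlen_t)C * H * W * B);
  double *xp = x.begin();
  const double *op = cols.begin();
  const int rows = C * k * k;
  for (int b = 0; b < B; ++b) {
    double *xb = xp + (R_xlen_t)b * C * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double *col = op + (R_xlen_t)rows * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (iw < 0 || iw >= W || ih < 0 || ih >= H) {
              r += C;
            } else {
              double *dst = xb + (R_xlen_t)C * (iw * H + ih);
              for (int c = 0; c < C; ++c) dst[c] += col[r++];
            }
          }
        }
      }
    }
  }
  return x;
}

// Gather all valid 3-frame time windows of x [C,H,W,T,B] into a
// channels-first array [3C,H,W,(T-2)*B]; slot (T-2)*b + ot holds frames
// ot..ot+2 of sample b, out channel = c + C*dt.
// [[Rcpp::export]]
NumericVector gather_tw(NumericVector x, int C, int H, int W, int T, int B) {
  const int nt = T - 2;
  NumericVector out((R_xlen_t)3 * C * H * W * nt * B);
  double *op = out.begin();
  const double *xp = x.begin();
  const R_xlen_t plane = (R_xlen_t)C * H * W;
  for (int b = 0; b < B; ++b) {
    for (int ot = 0; ot < nt; ++ot) {
      double *slot = op + (R_xlen_t)3 * plane * (nt * b + ot);
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double *dst = slot + (R_xlen_t)3 * C * (w * H + h);
          for (int dt = 0; dt < 3; ++dt) {
            const double *src = xp + (R_xlen_t)C *
              (h + (R_xlen_t)H * (w + (R_xlen_t)W * ((ot + dt) + (R_xlen_t)T * b)));
            std::memcpy(dst + C * dt, src, C * sizeof(double));
          }
        }
      }
    }
  }
  return out;
}

// Joint max-pooling over the three time slots produced by gather_tw's batch
// layout (slot 3b + t) and a k x k spatial window. y is [C,H,W,3B]; returns
// pooled [C,Ho,Wo,B] and the argmax as a linear index into y.
// [[Rcpp::export]]
List maxpool_t3m(NumericVector y, int C, int H, int W, int B,
                 int k, int pad, int stride, int Ho, int Wo) {
  NumericVector out((R_xlen_t)C * Ho * Wo * B);
  NumericVector amax((R_xlen_t)C * Ho * Wo * B);
  const double *yp = y.begin();
  double *op = out.begin(); double *ap = amax.begin();
  std::vector<double> bestv(C);
  std::vector<R_xlen_t> besti(C);
  const R_xlen_t plane = (R_xlen_t)C * H * W;
  for (int b = 0; b < B; ++b) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        std::fill(bestv.begin(), bestv.end(), -1e300);
        for (int t = 0; t < 3; ++t) {
          const double *slot = yp + plane * (3 * (R_xlen_t)b + t);
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const R_xlen_t base = (R_xlen_t)C * (iw * H + ih);
              const double *src = slot + base;
              const R_xlen_t gbase = plane * (3 * (R_xlen_t)b + t) + base;
              for (int c = 0; c < C; ++c) {
                if (src[c] > bestv[c]) { bestv[c] = src[c]; besti[c] = gbase + c; }
              }
            }
          }
        }
        double *o = op + (R_xlen_t)C * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        double *a = ap + (R_xlen_t)C * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        for (int c = 0; c < C; ++c) { o[c] = bestv[c]; a[c] = (double)besti[c]; }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// Single-slice spatial max pooling (k x k, stride, pad) on [C,H,W,B].
// [[Rcpp::export]]
List maxpool2(NumericVector y, int C, int H, int W, int B,
              int k, int pad, int stride, int Ho, int Wo) {
  NumericVector out((R_xlen_t)C * Ho * Wo * B);
  NumericVector amax((R_xlen_t)C * Ho * Wo * B);
  const double *yp = y.begin();
  double *op = out.begin(); double *ap = amax.begin();
  std::vector<double> bestv(C);
  std::vector<R_xlen_t> besti(C);
  for (int b = 0; b < B; ++b) {
    const double *yb = yp + (R_xlen_t)C * H * W * b;
    const R_xlen_t boff = (R_xlen_t)C * H * W * b;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        std::fill(bestv.begin(), bestv.end(), -1e300);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            const R_xlen_t base = (R_xlen_t)C * (iw * H + ih);
            const double *src = yb + base;
            for (int c = 0; c < C; ++c) {
              if (src[c] > bestv[c]) { bestv[c] = src[c]; besti[c] = boff + base + c; }
            }
          }
        }
        double *o = op + (R_xlen_t)C * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        double *a = ap + (R_xlen_t)C * ((R_xlen_t)b * Ho * Wo + ow * Ho + oh);
        for (int c = 0; c < C; ++c) { o[c] = bestv[c]; a[c] = (double)besti[c]; }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// Scatter pooled gradients back through a max pool; returns the gradient
// vector (length total_len) over the pooled input.
// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector grad, NumericVector amax,
                          double total_len) {
  NumericVector gx((R_xlen_t)total_len);
  const R_xlen_t n = grad.size();
  for (R_xlen_t i = 0; i < n; ++i) gx[(R_xlen_t)amax[i]] += grad[i];
  return gx;
}

// In-place variant of maxpool_bwd: zeroes and refills a preallocated
// gradient buffer.
// [[Rcpp::export]]
void maxpool_bwd_into(NumericVector gx, NumericVector grad,
                      NumericVector amax) {
  std::memset(gx.begin(), 0, gx.size() * sizeof(double));
  const R_xlen_t n = grad.size();
  for (R_xlen_t i = 0; i < n; ++i) gx[(R_xlen_t)amax[i]] += grad[i];
}
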