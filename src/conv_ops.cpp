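// Batched 2-D convolution forward/backward via im2col + GEMM, with fused
// ReLU. Array layout follows R column-major arrays: inputs (H, W, C, N),
// weights (k, k, Cin, Cout), outputs (Ho, Wo, Cout, N).
//
// The patch matrix is kept as (P x R) with P = Ho*Wo spatial positions and
// R = k*k*C patch entries, so both the x reads and the cols writes run
// down contiguous memory for stride-1 height traversal.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// cols(p, r): p = hi + Ho*wi, r = ki + k*kj + k*k*c
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        double* dst = cols.colptr(r);
        for (int wi = 0; wi < Wo; ++wi) {
          const int wsrc = wi * stride + kj - pad;
          if (wsrc < 0 || wsrc >= W) {
            for (int hi = 0; hi < Ho; ++hi) dst[hi + (size_t)Ho * wi] = 0.0;
            continue;
          }
          const double* src = x + (size_t)H * (wsrc + (size_t)W * c);
          for (int hi = 0; hi < Ho; ++hi) {
            const int hsrc = hi * stride + ki - pad;
            dst[hi + (size_t)Ho * wi] =
              (hsrc >= 0 && hsrc < H) ? src[hsrc] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, double* x) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        const double* src = cols.colptr(r);
        for (int wi = 0; wi < Wo; ++wi) {
          const int wsrc = wi * stride + kj - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          double* dst = x + (size_t)H * (wsrc + (size_t)W * c);
          for (int hi = 0; hi < Ho; ++hi) {
            const int hsrc = hi * stride + ki - pad;
            if (hsrc >= 0 && hsrc < H) dst[hsrc] += src[hi + (size_t)Ho * wi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad,
                             bool relu = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("x and w must be 4-d arrays");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input channel mismatch");
  if (b.size() != Cout) stop("bias length mismatch");
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("output dimensions collapse to zero");
  const int P = Ho * Wo, R = k * k * C;

  arma::mat Wmat(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::rowvec bias(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols(P, R);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    arma::mat out(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    out = cols * Wmat;
    out.each_row() += bias;
    if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  return y;
}

// Backward pass. `y` is the layer's cached forward output (post-ReLU when
// relu = TRUE); with relu = TRUE the incoming dy is gated by y > 0 before
// use. Set want_dx = false to skip the input gradient (first layer).
// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector y,
                     NumericVector dy, int stride, int pad,
                     bool relu = false, bool want_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Cout || yd[3] != N) stop("dy shape mismatch");
  if (y.size() != dy.size()) stop("y/dy size mismatch");
  const int P = Ho * Wo, R = k * k * C;

  arma::mat Wmat(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat dW(R, Cout, arma::fill::zeros);
  arma::rowvec dB(Cout, arma::fill::zeros);
  NumericVector dx(want_dx ? (size_t)H * W * C * N : 0);
  if (want_dx) dx.attr("dim") = xd;

  arma::mat cols(P, R);
  arma::mat dYg(P, Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)P * Cout * n;
    if (relu) {
      const double* yn = y.begin() + (size_t)P * Cout * n;
      double* g = dYg.memptr();
      for (size_t i = 0; i < (size_t)P * Cout; ++i)
        g[i] = yn[i] > 0.0 ? dyn[i] : 0.0;
    } else {
      std::copy(dyn, dyn + (size_t)P * Cout, dYg.memptr());
    }
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    dW += cols.t() * dYg;
    dB += arma::sum(dYg, 0);
    if (want_dx) {
      arma::mat dcols = dYg * Wmat.t();   // (P x R)
      col2im(dcols, H, W, C, k, stride, pad,
             dx.begin() + (size_t)H * W * C * n);
    }
  }

  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  NumericVector dbv(dB.begin(), dB.end());
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}
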