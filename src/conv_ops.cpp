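// im2col/GEMM 2-D convolution engine (forward + backward), dual precision.
//
// Tensors have physical dim (H, W, C, N) -- the same memory order as a
// row-major NCHW tensor, so spatial columns are contiguous.  Weights arrive
// as a (kh*kw*C) x F double matrix whose row index is ki + kh*kj + kh*kw*c
// (0-based), i.e. the natural flattening of an R array with dim
// (kh, kw, C, F); they are cast once per call when the activations are
// single precision.  "Same" padding: pad = (k-1)/2, so the output side is
// ceil(side/stride).  Weight gradients are returned in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "tensor_common.h"
using namespace Rcpp;

// Fill cols (M x K, M = Ho*Wo, column-major) for one sample.
template <typename T>
static void im2col_one(const T* x, int H, int W, int C,
                       int kh, int kw, int s, int ph, int pw,
                       int Ho, int Wo, T* cols)
{
  const int M = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        T* col = cols + (size_t)M * ((size_t)c * kh * kw + (size_t)kj * kh + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * s - pw + kj;
          T* dst = col + (size_t)wo * Ho;
          if (w < 0 || w >= W) { std::fill(dst, dst + Ho, (T)0); continue; }
          const T* xw = xc + (size_t)w * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * s - ph + ki;
            dst[ho] = (h >= 0 && h < H) ? xw[h] : (T)0;
          }
        }
      }
    }
  }
}

// Scatter-accumulate cols gradient (M x K) back onto dx for one sample.
template <typename T>
static void col2im_one(const T* cols, int H, int W, int C,
                       int kh, int kw, int s, int ph, int pw,
                       int Ho, int Wo, T* dx)
{
  const int M = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    T* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const T* col = cols + (size_t)M * ((size_t)c * kh * kw + (size_t)kj * kh + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * s - pw + kj;
          if (w < 0 || w >= W) continue;
          T* xw = xc + (size_t)w * H;
          const T* src = col + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * s - ph + ki;
            if (h >= 0 && h < H) xw[h] += src[ho];
          }
        }
      }
    }
  }
}

static inline int out_side(int side, int s) { return (side + s - 1) / s; }

template <typename T>
SEXP conv2d_fw_t(SEXP xs, const IntegerVector& xdim, const NumericMatrix& wm,
                 int kh, int kw, int stride)
{
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int F = wm.ncol();
  const int K = kh * kw * C;
  if (wm.nrow() != K) stop("weight matrix rows (%d) != kh*kw*C (%d)", wm.nrow(), K);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Ho = out_side(H, stride), Wo = out_side(W, stride);
  const int M = Ho * Wo;

  IntegerVector odim = IntegerVector::create(Ho, Wo, F, N);
  Shield<SEXP> y(alloc_tensor<T>((R_xlen_t)M * F * N, odim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);

  arma::Mat<T> W_(K, F);
  for (int j = 0; j < F; ++j)
    for (int i = 0; i < K; ++i) W_(i, j) = (T)wm(i, j);
  arma::Mat<T> cols(M, K);
  const bool direct = (kh == 1 && kw == 1 && stride == 1);

  for (int n = 0; n < N; ++n) {
    const T* xn = px + (size_t)n * H * W * C;
    arma::Mat<T> Y(py + (size_t)n * M * F, M, F, false, true);
    if (direct) {
      const arma::Mat<T> X(const_cast<T*>(xn), M, C, false, true);
      Y = X * W_;
    } else {
      im2col_one(xn, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, cols.memptr());
      Y = cols * W_;
    }
  }
  return y;
}
// [[Rcpp::export]]
SEXP conv2d_fw_cpp(SEXP x, const IntegerVector& xdim, const NumericMatrix& wm,
                   int kh, int kw, int stride)
{
  return DISPATCH_T(x, conv2d_fw_t<double>(x, xdim, wm, kh, kw, stride),
                    conv2d_fw_t<float>(x, xdim, wm, kh, kw, stride));
}

template <typename T>
List conv2d_bw_t(SEXP xs, const IntegerVector& xdim, const NumericMatrix& wm,
                 SEXP dys, int kh, int kw, int stride, bool need_dx)
{
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int F = wm.ncol();
  const int K = kh * kw * C;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Ho = out_side(H, stride), Wo = out_side(W, stride);
  const int M = Ho * Wo;

  Shield<SEXP> dx(need_dx ? alloc_tensor<T>((R_xlen_t)H * W * C * N, xdim)
                          : R_NilValue);
  T* pdx = need_dx ? TensorType<T>::ptr(dx) : (T*)0;
  if (need_dx) std::fill(pdx, pdx + (R_xlen_t)H * W * C * N, (T)0);
  const T* px = TensorType<T>::cptr(xs);
  const T* pd = TensorType<T>::cptr(dys);

  arma::Mat<T> W_(K, F);
  for (int j = 0; j < F; ++j)
    for (int i = 0; i < K; ++i) W_(i, j) = (T)wm(i, j);
  arma::Mat<T> dW(K, F, arma::fill::zeros);
  arma::Mat<T> cols(M, K), dcols(M, K);
  const bool direct = (kh == 1 && kw == 1 && stride == 1);

  for (int n = 0; n < N; ++n) {
    const T* xn = px + (size_t)n * H * W * C;
    const arma::Mat<T> dY(const_cast<T*>(pd) + (size_t)n * M * F, M, F, false, true);
    if (direct) {
      const arma::Mat<T> X(const_cast<T*>(xn), M, C, false, true);
      dW += X.t() * dY;
      if (need_dx) {
        arma::Mat<T> dX(pdx + (size_t)n * M * C, M, C, false, true);
        dX = dY * W_.t();
      }
    } else {
      im2col_one(xn, H, W, C, kh, kw, stride, ph, pw, Ho, Wo, cols.memptr());
      dW += cols.t() * dY;
      if (need_dx) {
        dcols = dY * W_.t();
        col2im_one(dcols.memptr(), H, W, C, kh, kw, stride, ph, pw, Ho, Wo,
                   pdx + (size_t)n * H * W * C);
      }
    }
  }
  NumericMatrix dWout(K, F);
  for (int j = 0; j < F; ++j)
    for (int i = 0; i < K; ++i) dWout(i, j) = (double)dW(i, j);
  return List::create(Named("dx") = (SEXP)dx, Named("dw") = dWout);
}
// [[Rcpp::export]]
List conv2d_bw_cpp(SEXP x, const IntegerVector& xdim, const NumericMatrix& wm,
                   SEXP dy, int kh, int kw, int stride, bool need_dx)
{
  return DISPATCH_T(x,
    conv2d_bw_t<double>(x, xdim, wm, dy, kh, kw, stride, need_dx),
    conv2d_bw_t<float>(x, xdim, wm, dy, kh, kw, stride, need_dx));
}
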