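// Fused elementwise kernels for the training loop, in dual precision.
// Tensors have physical dim (H, W, C, N); see tensor_common.h for the
// single-precision representation.  "cn" matrices are C x N doubles;
// per-channel parameters of length cpar < C recycle over the channel axis
// (cpar divides C), matching R recycling.

#include "tensor_common.h"
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// The training loop churns through large (100+ MB) activation buffers.  By
// default glibc serves these with mmap and returns them to the OS on free,
// so every step pays page-fault + zeroing costs again.  Raising the mmap
// threshold keeps the buffers in the heap for reuse.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

static inline R_xlen_t nel(const IntegerVector& d) {
  return (R_xlen_t)d[0] * d[1] * d[2] * d[3];
}

// ---- precision conversion --------------------------------------------------

// [[Rcpp::export]]
SEXP to_float_cpp(SEXP x, const IntegerVector& dim) {
  if (is_float_tensor(x)) return x;
  const R_xlen_t n = nel(dim);
  SEXP out = alloc_tensor<float>(n, dim);
  PROTECT(out);
  const double* px = REAL(x);
  float* py = TensorType<float>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i) py[i] = (float)px[i];
  UNPROTECT(1);
  return out;
}

// [[Rcpp::export]]
SEXP from_float_cpp(SEXP x, const IntegerVector& dim) {
  if (!is_float_tensor(x)) return x;
  const R_xlen_t n = nel(dim);
  SEXP out = alloc_tensor<double>(n, dim);
  PROTECT(out);
  const float* px = TensorType<float>::cptr(x);
  double* py = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) py[i] = (double)px[i];
  UNPROTECT(1);
  return out;
}

// ---- simple elementwise ----------------------------------------------------

template <typename T>
SEXP relu_fw_t(SEXP x, const IntegerVector& dim) {
  const R_xlen_t n = nel(dim);
  Shield<SEXP> out(alloc_tensor<T>(n, dim));
  const T* px = TensorType<T>::cptr(x);
  T* py = TensorType<T>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : (T)0;
  return out;
}
// [[Rcpp::export]]
SEXP ew_relu_fw(SEXP x, const IntegerVector& dim) {
  return DISPATCH_T(x, relu_fw_t<double>(x, dim), relu_fw_t<float>(x, dim));
}

template <typename T>
SEXP relu_bw_t(SEXP x, SEXP dy, const IntegerVector& dim) {
  const R_xlen_t n = nel(dim);
  Shield<SEXP> out(alloc_tensor<T>(n, dim));
  const T* px = TensorType<T>::cptr(x);
  const T* pd = TensorType<T>::cptr(dy);
  T* po = TensorType<T>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? pd[i] : (T)0;
  return out;
}
// [[Rcpp::export]]
SEXP ew_relu_bw(SEXP x, SEXP dy, const IntegerVector& dim) {
  return DISPATCH_T(x, relu_bw_t<double>(x, dy, dim),
                    relu_bw_t<float>(x, dy, dim));
}

template <typename T>
SEXP sigmoid_t(SEXP x, const IntegerVector& dim) {
  const R_xlen_t n = nel(dim);
  Shield<SEXP> out(alloc_tensor<T>(n, dim));
  const T* px = TensorType<T>::cptr(x);
  T* py = TensorType<T>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i)
    py[i] = (T)(1.0 / (1.0 + std::exp(-(double)px[i])));
  return out;
}
// [[Rcpp::export]]
SEXP ew_sigmoid(SEXP x, const IntegerVector& dim) {
  return DISPATCH_T(x, sigmoid_t<double>(x, dim), sigmoid_t<float>(x, dim));
}

template <typename T>
SEXP relu_add_t(SEXP x, SEXP e, const IntegerVector& dim) {
  const R_xlen_t n = nel(dim);
  Shield<SEXP> out(alloc_tensor<T>(n, dim));
  const T* px = TensorType<T>::cptr(x);
  const T* pe = TensorType<T>::cptr(e);
  T* py = TensorType<T>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i)
    py[i] = (px[i] > 0 ? px[i] : (T)0) + pe[i];
  return out;
}
// out = relu(x) + e  (residual identity path of Block1)
// [[Rcpp::export]]
SEXP ew_relu_add(SEXP x, SEXP e, const IntegerVector& dim) {
  return DISPATCH_T(x, relu_add_t<double>(x, e, dim),
                    relu_add_t<float>(x, e, dim));
}

template <typename T>
SEXP add_t(SEXP a, SEXP b, const IntegerVector& dim) {
  const R_xlen_t n = nel(dim);
  Shield<SEXP> out(alloc_tensor<T>(n, dim));
  const T* pa = TensorType<T>::cptr(a);
  const T* pb = TensorType<T>::cptr(b);
  T* py = TensorType<T>::ptr(out);
  for (R_xlen_t i = 0; i < n; ++i) py[i] = pa[i] + pb[i];
  return out;
}
// [[Rcpp::export]]
SEXP ew_add(SEXP a, SEXP b, const IntegerVector& dim) {
  return DISPATCH_T(a, add_t<double>(a, b, dim), add_t<float>(a, b, dim));
}

// ---- batch normalization ---------------------------------------------------

template <typename T>
List bn_fw_train_t(SEXP xs, const IntegerVector& dim,
                   const NumericVector& gamma, const NumericVector& beta,
                   double eps, bool relu) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  const double cnt = (double)HW * N;
  NumericVector mean(C), var(C), istd(C);
  const T* px = TensorType<T>::cptr(xs);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      double s = 0, q = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        s += p[i]; q += (double)p[i] * p[i];
      }
      mean[c] += s; var[c] += q;
    }
  for (int c = 0; c < C; ++c) {
    mean[c] /= cnt;
    var[c] = var[c] / cnt - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  Shield<SEXP> y(alloc_tensor<T>(nel(dim), dim));
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] * istd[c];
      const double sh = beta[c] - mean[c] * sc;
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      T* q = py + ((R_xlen_t)n * C + c) * HW;
      if (relu)
        for (R_xlen_t i = 0; i < HW; ++i) {
          const double v = p[i] * sc + sh;
          q[i] = (T)(v > 0 ? v : 0.0);
        }
      else
        for (R_xlen_t i = 0; i < HW; ++i) q[i] = (T)(p[i] * sc + sh);
    }
  return List::create(Named("out") = (SEXP)y, Named("mean") = mean,
                      Named("var") = var, Named("istd") = istd);
}
// training-mode batch norm: one stats pass + one apply pass; optionally
// fuses the following ReLU (the backward recomputes the mask)
// [[Rcpp::export]]
List bn_fw_train_cpp(SEXP x, const IntegerVector& dim,
                     const NumericVector& gamma, const NumericVector& beta,
                     double eps, bool relu) {
  return DISPATCH_T(x, bn_fw_train_t<double>(x, dim, gamma, beta, eps, relu),
                    bn_fw_train_t<float>(x, dim, gamma, beta, eps, relu));
}

template <typename T>
SEXP bn_fw_eval_t(SEXP xs, const IntegerVector& dim,
                  const NumericVector& gamma, const NumericVector& beta,
                  const NumericVector& rmean, const NumericVector& rvar,
                  double eps, bool relu) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  Shield<SEXP> y(alloc_tensor<T>(nel(dim), dim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] / std::sqrt(rvar[c] + eps);
      const double sh = beta[c] - rmean[c] * sc;
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      T* q = py + ((R_xlen_t)n * C + c) * HW;
      if (relu)
        for (R_xlen_t i = 0; i < HW; ++i) {
          const double v = p[i] * sc + sh;
          q[i] = (T)(v > 0 ? v : 0.0);
        }
      else
        for (R_xlen_t i = 0; i < HW; ++i) q[i] = (T)(p[i] * sc + sh);
    }
  return y;
}
// [[Rcpp::export]]
SEXP bn_fw_eval_cpp(SEXP x, const IntegerVector& dim,
                    const NumericVector& gamma, const NumericVector& beta,
                    const NumericVector& rmean, const NumericVector& rvar,
                    double eps, bool relu) {
  return DISPATCH_T(x,
    bn_fw_eval_t<double>(x, dim, gamma, beta, rmean, rvar, eps, relu),
    bn_fw_eval_t<float>(x, dim, gamma, beta, rmean, rvar, eps, relu));
}

template <typename T>
List bn_bw_t(SEXP xs, SEXP dys, const IntegerVector& dim,
             const NumericVector& mean, const NumericVector& istd,
             const NumericVector& gamma, const NumericVector& beta,
             bool relu) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  const double cnt = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  const T* px = TensorType<T>::cptr(xs);
  const T* pd = TensorType<T>::cptr(dys);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      const T* d = pd + ((R_xlen_t)n * C + c) * HW;
      const double sc = gamma[c] * istd[c];
      const double sh = beta[c] - mean[c] * sc;
      double s = 0, q = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double dv = (!relu || p[i] * sc + sh > 0) ? (double)d[i] : 0.0;
        s += dv;
        q += dv * (p[i] - mean[c]);
      }
      dbeta[c] += s; dgamma[c] += q * istd[c];
    }
  Shield<SEXP> dx(alloc_tensor<T>(nel(dim), dim));
  T* pdx = TensorType<T>::ptr(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c] * istd[c];
      const double sh = beta[c] - mean[c] * g;
      const double mdb = dbeta[c] / cnt;
      const double mdg = dgamma[c] / cnt;
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      const T* d = pd + ((R_xlen_t)n * C + c) * HW;
      T* o = pdx + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double xh = (p[i] - mean[c]) * istd[c];
        const double dv = (!relu || p[i] * g + sh > 0) ? (double)d[i] : 0.0;
        o[i] = (T)(g * (dv - mdb - xh * mdg));
      }
    }
  return List::create(Named("dx") = (SEXP)dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
// [[Rcpp::export]]
List bn_bw_cpp(SEXP x, SEXP dy, const IntegerVector& dim,
               const NumericVector& mean, const NumericVector& istd,
               const NumericVector& gamma, const NumericVector& beta,
               bool relu) {
  return DISPATCH_T(x,
    bn_bw_t<double>(x, dy, dim, mean, istd, gamma, beta, relu),
    bn_bw_t<float>(x, dy, dim, mean, istd, gamma, beta, relu));
}

// ---- per-(channel, sample) reductions and broadcasts ----------------------

template <typename T>
NumericMatrix cn_sum_t(SEXP xs, const IntegerVector& dim) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  NumericMatrix s(C, N);
  const T* px = TensorType<T>::cptr(xs);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      double acc = 0;
      for (R_xlen_t i = 0; i < HW; ++i) acc += p[i];
      s(c, n) = acc;
    }
  return s;
}
// [[Rcpp::export]]
NumericMatrix cn_sum_cpp(SEXP x, const IntegerVector& dim) {
  return DISPATCH_T(x, cn_sum_t<double>(x, dim), cn_sum_t<float>(x, dim));
}

template <typename T>
NumericMatrix cn_dot_t(SEXP xs, SEXP ys, const IntegerVector& dim) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  NumericMatrix s(C, N);
  const T* px = TensorType<T>::cptr(xs);
  const T* py = TensorType<T>::cptr(ys);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      double acc = 0;
      for (R_xlen_t i = 0; i < HW; ++i)
        acc += (double)px[off + i] * py[off + i];
      s(c, n) = acc;
    }
  return s;
}
// [[Rcpp::export]]
NumericMatrix cn_dot_cpp(SEXP x, SEXP y, const IntegerVector& dim) {
  return DISPATCH_T(x, cn_dot_t<double>(x, y, dim), cn_dot_t<float>(x, y, dim));
}

template <typename T>
SEXP cn_scale_t(SEXP xs, const IntegerVector& dim, const NumericVector& g) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  Shield<SEXP> y(alloc_tensor<T>(nel(dim), dim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double gc = g[(R_xlen_t)n * C + c];
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) py[off + i] = (T)(px[off + i] * gc);
    }
  return y;
}
// y = x * g[c,n]
// [[Rcpp::export]]
SEXP cn_scale_cpp(SEXP x, const IntegerVector& dim, const NumericVector& g) {
  return DISPATCH_T(x, cn_scale_t<double>(x, dim, g),
                    cn_scale_t<float>(x, dim, g));
}

template <typename T>
SEXP cn_scale_add_t(SEXP xs, const IntegerVector& dim, const NumericVector& g,
                    const NumericVector& a) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  Shield<SEXP> y(alloc_tensor<T>(nel(dim), dim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double gc = g[(R_xlen_t)n * C + c];
      const double ac = a[(R_xlen_t)n * C + c];
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i)
        py[off + i] = (T)(px[off + i] * gc + ac);
    }
  return y;
}
// y = x * g[c,n] + a[c,n]
// [[Rcpp::export]]
SEXP cn_scale_add_cpp(SEXP x, const IntegerVector& dim, const NumericVector& g,
                      const NumericVector& a) {
  return DISPATCH_T(x, cn_scale_add_t<double>(x, dim, g, a),
                    cn_scale_add_t<float>(x, dim, g, a));
}

// ---- channel gather / merge ------------------------------------------------

template <typename T>
SEXP chan_gather_t(SEXP xs, const IntegerVector& dim, const IntegerVector& map) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  const int Co = map.size();
  IntegerVector odim = IntegerVector::create(dim[0], dim[1], Co, N);
  Shield<SEXP> y(alloc_tensor<T>((R_xlen_t)HW * Co * N, odim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Co; ++j)
      std::copy(px + ((R_xlen_t)n * C + map[j] - 1) * HW,
                px + ((R_xlen_t)n * C + map[j]) * HW,
                py + ((R_xlen_t)n * Co + j) * HW);
  return y;
}
// channel gather: y[,,j,] = x[,,map[j],]  (map 1-based)
// [[Rcpp::export]]
SEXP chan_gather_cpp(SEXP x, const IntegerVector& dim, const IntegerVector& map) {
  return DISPATCH_T(x, chan_gather_t<double>(x, dim, map),
                    chan_gather_t<float>(x, dim, map));
}

template <typename T>
SEXP chan_merge_t(SEXP x1, SEXP x2, const IntegerVector& dimh,
                  const IntegerVector& map) {
  const R_xlen_t HW = (R_xlen_t)dimh[0] * dimh[1];
  const int C1 = dimh[2], N = dimh[3];
  const int C = map.size();
  IntegerVector odim = IntegerVector::create(dimh[0], dimh[1], C, N);
  Shield<SEXP> y(alloc_tensor<T>((R_xlen_t)HW * C * N, odim));
  const T* p1 = TensorType<T>::cptr(x1);
  const T* p2 = TensorType<T>::cptr(x2);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < C; ++j) {
      const T* src = (map[j] <= C1)
        ? p1 + ((R_xlen_t)n * C1 + map[j] - 1) * HW
        : p2 + ((R_xlen_t)n * (C - C1) + map[j] - C1 - 1) * HW;
      std::copy(src, src + HW, py + ((R_xlen_t)n * C + j) * HW);
    }
  return y;
}
// merge two tensors along channels: out channel j takes x1 channel map[j] if
// map[j] <= C1, else x2 channel map[j]-C1  (map 1-based)
// [[Rcpp::export]]
SEXP chan_merge_cpp(SEXP x1, SEXP x2, const IntegerVector& dimh,
                    const IntegerVector& map) {
  return DISPATCH_T(x1, chan_merge_t<double>(x1, x2, dimh, map),
                    chan_merge_t<float>(x1, x2, dimh, map));
}

// ---- fully fused Shuffle Attention ----------------------------------------
// Per output channel j, src[j] (1-based) names the source channel and
// br[src] the branch: 1 = channel attention (gate g1[src,n]); 2 = spatial
// attention (group-norm statistics mu/istd[src,n], affine gate wc/bc[src]).
// Neither the half tensors, the normalized tensor nor the gate maps are
// materialized.

template <typename T>
List sa_stats_t(SEXP xs, const IntegerVector& dim) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  NumericMatrix s(C, N), q(C, N);
  const T* px = TensorType<T>::cptr(xs);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const T* p = px + ((R_xlen_t)n * C + c) * HW;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        a += p[i]; b += (double)p[i] * p[i];
      }
      s(c, n) = a; q(c, n) = b;
    }
  return List::create(Named("s") = s, Named("q") = q);
}
// one pass: per-(c,n) sums and sums of squares
// [[Rcpp::export]]
List sa_stats_cpp(SEXP x, const IntegerVector& dim) {
  return DISPATCH_T(x, sa_stats_t<double>(x, dim), sa_stats_t<float>(x, dim));
}

template <typename T>
SEXP sa_apply_fw_t(SEXP xs, const IntegerVector& dim, const IntegerVector& src,
                   const IntegerVector& br, const NumericMatrix& g1,
                   const NumericMatrix& mu, const NumericMatrix& istd,
                   const NumericVector& wc, const NumericVector& bc) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  Shield<SEXP> y(alloc_tensor<T>(nel(dim), dim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < C; ++j) {
      const int sc = src[j] - 1;
      const T* p = px + ((R_xlen_t)n * C + sc) * HW;
      T* o = py + ((R_xlen_t)n * C + j) * HW;
      if (br[sc] == 1) {
        const double g = g1(sc, n);
        for (R_xlen_t i = 0; i < HW; ++i) o[i] = (T)(p[i] * g);
      } else {
        const double m = mu(sc, n), is = istd(sc, n);
        const double w = wc[sc], b = bc[sc];
        for (R_xlen_t i = 0; i < HW; ++i) {
          const double xn = (p[i] - m) * is;
          o[i] = (T)(p[i] / (1.0 + std::exp(-(w * xn + b))));
        }
      }
    }
  return y;
}
// [[Rcpp::export]]
SEXP sa_apply_fw_cpp(SEXP x, const IntegerVector& dim, const IntegerVector& src,
                     const IntegerVector& br, const NumericMatrix& g1,
                     const NumericMatrix& mu, const NumericMatrix& istd,
                     const NumericVector& wc, const NumericVector& bc) {
  return DISPATCH_T(x,
    sa_apply_fw_t<double>(x, dim, src, br, g1, mu, istd, wc, bc),
    sa_apply_fw_t<float>(x, dim, src, br, g1, mu, istd, wc, bc));
}

template <typename T>
List sa_bw1_t(SEXP dys, SEXP xs, const IntegerVector& dim,
              const IntegerVector& src, const IntegerVector& br,
              const NumericMatrix& mu, const NumericMatrix& istd,
              const NumericVector& wc, const NumericVector& bc) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  NumericMatrix A1(C, N), A2(C, N);
  const T* pd = TensorType<T>::cptr(dys);
  const T* px = TensorType<T>::cptr(xs);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < C; ++j) {
      const int sc = src[j] - 1;
      const T* p = px + ((R_xlen_t)n * C + sc) * HW;
      const T* d = pd + ((R_xlen_t)n * C + j) * HW;
      if (br[sc] == 1) {
        double a = 0;
        for (R_xlen_t i = 0; i < HW; ++i) a += (double)d[i] * p[i];
        A1(sc, n) = a;
      } else {
        const double m = mu(sc, n), is = istd(sc, n);
        const double w = wc[sc], b = bc[sc];
        double a1 = 0, a2 = 0;
        for (R_xlen_t i = 0; i < HW; ++i) {
          const double xn = (p[i] - m) * is;
          const double g = 1.0 / (1.0 + std::exp(-(w * xn + b)));
          const double dz = (double)d[i] * p[i] * g * (1.0 - g);
          a1 += dz * xn; a2 += dz;
        }
        A1(sc, n) = a1; A2(sc, n) = a2;
      }
    }
  return List::create(Named("A1") = A1, Named("A2") = A2);
}
// backward pass 1: channel branch A1 = sum dy*x; spatial branch
// A1 = sum dz*xn, A2 = sum dz with dz = dy*x*g*(1-g)
// [[Rcpp::export]]
List sa_bw1_cpp(SEXP dy, SEXP x, const IntegerVector& dim,
                const IntegerVector& src, const IntegerVector& br,
                const NumericMatrix& mu, const NumericMatrix& istd,
                const NumericVector& wc, const NumericVector& bc) {
  return DISPATCH_T(x,
    sa_bw1_t<double>(dy, x, dim, src, br, mu, istd, wc, bc),
    sa_bw1_t<float>(dy, x, dim, src, br, mu, istd, wc, bc));
}

template <typename T>
SEXP sa_bw2_t(SEXP dys, SEXP xs, const IntegerVector& dim,
              const IntegerVector& src, const IntegerVector& br,
              const NumericMatrix& g1, const NumericMatrix& mu,
              const NumericMatrix& istd, const NumericVector& wc,
              const NumericVector& bc, const NumericMatrix& add1,
              const NumericMatrix& m1, const NumericMatrix& m2) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  Shield<SEXP> dx(alloc_tensor<T>(nel(dim), dim));
  const T* pd = TensorType<T>::cptr(dys);
  const T* px = TensorType<T>::cptr(xs);
  T* po = TensorType<T>::ptr(dx);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < C; ++j) {
      const int sc = src[j] - 1;
      const T* p = px + ((R_xlen_t)n * C + sc) * HW;
      const T* d = pd + ((R_xlen_t)n * C + j) * HW;
      T* o = po + ((R_xlen_t)n * C + sc) * HW;
      if (br[sc] == 1) {
        const double g = g1(sc, n), ad = add1(sc, n);
        for (R_xlen_t i = 0; i < HW; ++i) o[i] = (T)(d[i] * g + ad);
      } else {
        const double m = mu(sc, n), is = istd(sc, n);
        const double w = wc[sc], b = bc[sc];
        const double u1 = m1(sc, n), u2 = m2(sc, n);
        for (R_xlen_t i = 0; i < HW; ++i) {
          const double xn = (p[i] - m) * is;
          const double g = 1.0 / (1.0 + std::exp(-(w * xn + b)));
          const double dz = (double)d[i] * p[i] * g * (1.0 - g);
          o[i] = (T)(is * (dz * w - u1 - xn * u2) + d[i] * g);
        }
      }
    }
  return dx;
}
// backward pass 2: writes dx at the source channel position.
// channel branch: dx = dy*g1 + add1[sc,n].
// spatial branch: dx = istd*(dz*wc - m1[sc,n] - xn*m2[sc,n]) + dy*g.
// [[Rcpp::export]]
SEXP sa_bw2_cpp(SEXP dy, SEXP x, const IntegerVector& dim,
                const IntegerVector& src, const IntegerVector& br,
                const NumericMatrix& g1, const NumericMatrix& mu,
                const NumericMatrix& istd, const NumericVector& wc,
                const NumericVector& bc, const NumericMatrix& add1,
                const NumericMatrix& m1, const NumericMatrix& m2) {
  return DISPATCH_T(x,
    sa_bw2_t<double>(dy, x, dim, src, br, g1, mu, istd, wc, bc, add1, m1, m2),
    sa_bw2_t<float>(dy, x, dim, src, br, g1, mu, istd, wc, bc, add1, m1, m2));
}

// ---- upsampling ------------------------------------------------------------
// Separable interpolation given per-axis source indices (1-based) and the
// fractional weight of the second source along each axis.

template <typename T>
SEXP upsample_fw_t(SEXP xs, const IntegerVector& dim,
                   const IntegerVector& h0, const IntegerVector& h1,
                   const NumericVector& th, const IntegerVector& w0,
                   const IntegerVector& w1, const NumericVector& tw) {
  const int H = dim[0], C = dim[2], N = dim[3];
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int Ho = h0.size(), Wo = w0.size();
  IntegerVector odim = IntegerVector::create(Ho, Wo, C, N);
  Shield<SEXP> y(alloc_tensor<T>((R_xlen_t)Ho * Wo * C * N, odim));
  const T* px = TensorType<T>::cptr(xs);
  T* py = TensorType<T>::ptr(y);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const T* p = px + cn * HW;
    T* o = py + cn * (R_xlen_t)Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const T* pa = p + (R_xlen_t)(w0[wo] - 1) * H;
      const T* pb = p + (R_xlen_t)(w1[wo] - 1) * H;
      const double t = tw[wo];
      T* oc = o + (R_xlen_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const int a = h0[ho] - 1, b = h1[ho] - 1;
        const double s = th[ho];
        const double va = (1 - t) * pa[a] + t * pb[a];
        const double vb = (1 - t) * pa[b] + t * pb[b];
        oc[ho] = (T)((1 - s) * va + s * vb);
      }
    }
  }
  return y;
}
// [[Rcpp::export]]
SEXP upsample_fw_cpp(SEXP x, const IntegerVector& dim,
                     const IntegerVector& h0, const IntegerVector& h1,
                     const NumericVector& th, const IntegerVector& w0,
                     const IntegerVector& w1, const NumericVector& tw) {
  return DISPATCH_T(x, upsample_fw_t<double>(x, dim, h0, h1, th, w0, w1, tw),
                    upsample_fw_t<float>(x, dim, h0, h1, th, w0, w1, tw));
}

template <typename T>
SEXP upsample_bw_t(SEXP dys, const IntegerVector& odim,
                   const IntegerVector& idim,
                   const IntegerVector& h0, const IntegerVector& h1,
                   const NumericVector& th, const IntegerVector& w0,
                   const IntegerVector& w1, const NumericVector& tw) {
  const int Ho = odim[0], Wo = odim[1], C = odim[2], N = odim[3];
  const int H = idim[0], W = idim[1];
  const R_xlen_t HWi = (R_xlen_t)H * W;
  Shield<SEXP> dx(alloc_tensor<T>(HWi * C * N, idim));
  const T* pd = TensorType<T>::cptr(dys);
  T* po = TensorType<T>::ptr(dx);
  std::fill(po, po + HWi * C * N, (T)0);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const T* d = pd + cn * (R_xlen_t)Ho * Wo;
    T* o = po + cn * HWi;
    for (int wo = 0; wo < Wo; ++wo) {
      T* oa = o + (R_xlen_t)(w0[wo] - 1) * H;
      T* ob = o + (R_xlen_t)(w1[wo] - 1) * H;
      const double t = tw[wo];
      const T* dc = d + (R_xlen_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const int a = h0[ho] - 1, b = h1[ho] - 1;
        const double s = th[ho];
        const double v = dc[ho];
        oa[a] += (T)((1 - t) * (1 - s) * v);
        oa[b] += (T)((1 - t) * s * v);
        ob[a] += (T)(t * (1 - s) * v);
        ob[b] += (T)(t * s * v);
      }
    }
  }
  return dx;
}
// [[Rcpp::export]]
SEXP upsample_bw_cpp(SEXP dy, const IntegerVector& odim,
                     const IntegerVector& idim,
                     const IntegerVector& h0, const IntegerVector& h1,
                     const NumericVector& th, const IntegerVector& w0,
                     const IntegerVector& w1, const NumericVector& tw) {
  return DISPATCH_T(dy,
    upsample_bw_t<double>(dy, odim, idim, h0, h1, th, w0, w1, tw),
    upsample_bw_t<float>(dy, odim, idim, h0, h1, th, w0, w1, tw));
}

// ---- loss ------------------------------------------------------------------

// mean binary cross-entropy of the sigmoid output against labels replicated
// across the channel axis, plus the gradient w.r.t. the pre-sigmoid
// activation ((p - y)/numel), in the output's precision.  y: (H, W, N).
template <typename T>
List bce_grad_t(SEXP ps, const IntegerVector& dim, const NumericVector& y,
                double eps) {
  const R_xlen_t HW = (R_xlen_t)dim[0] * dim[1];
  const int C = dim[2], N = dim[3];
  const double total = (double)HW * C * N;
  Shield<SEXP> dpre(alloc_tensor<T>((R_xlen_t)(HW * C * N), dim));
  const T* pp = TensorType<T>::cptr(ps);
  T* pd = TensorType<T>::ptr(dpre);
  double loss = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* py = y.begin() + (R_xlen_t)n * HW;
      const T* p = pp + ((R_xlen_t)n * C + c) * HW;
      T* d = pd + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) {
        double pv = p[i];
        if (pv < eps) pv = eps;
        if (pv > 1 - eps) pv = 1 - eps;
        loss -= py[i] * std::log(pv) + (1 - py[i]) * std::log(1 - pv);
        d[i] = (T)(((double)p[i] - py[i]) / total);
      }
    }
  return List::create(Named("loss") = loss / total,
                      Named("dpre") = (SEXP)dpre);
}
// [[Rcpp::export]]
List bce_grad_cpp(SEXP p, const IntegerVector& dim, const NumericVector& y,
                  double eps) {
  return DISPATCH_T(p, bce_grad_t<double>(p, dim, y, eps),
                    bce_grad_t<float>(p, dim, y, eps));
}
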