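// Shared helpers for the dual-precision tensor kernels.
//
// Engine tensors are either double R arrays (dim attribute) or raw vectors
// holding IEEE single-precision values (logical dims in attribute "fdim").
// Activations may be kept in single precision to halve memory traffic;
// parameters, statistics and gradient accumulators are always double.

#ifndef VESSELNET_TENSOR_COMMON_H
#define VESSELNET_TENSOR_COMMON_H

#include <Rcpp.h>

inline bool is_float_tensor(SEXP x) { return TYPEOF(x) == RAWSXP; }

template <typename T> struct TensorType;
template <> struct TensorType<double> {
  static SEXP alloc(R_xlen_t n) { return Rf_allocVector(REALSXP, n); }
  static double* ptr(SEXP x) { return REAL(x); }
  static const double* cptr(SEXP x) { return REAL(x); }
  static void set_dim(SEXP x, SEXP d) { Rf_setAttrib(x, R_DimSymbol, d); }
};
template <> struct TensorType<float> {
  static SEXP alloc(R_xlen_t n) { return Rf_allocVector(RAWSXP, 4 * n); }
  static float* ptr(SEXP x) { return reinterpret_cast<float*>(RAW(x)); }
  static const float* cptr(SEXP x) {
    return reinterpret_cast<const float*>(RAW(x));
  }
  static void set_dim(SEXP x, SEXP d) {
    Rf_setAttrib(x, Rf_install("fdim"), d);
  }
};

// allocate an output tensor of type T with the given logical dims
template <typename T>
SEXP alloc_tensor(R_xlen_t n, const Rcpp::IntegerVector& dim) {
  SEXP out = TensorType<T>::alloc(n);
  PROTECT(out);
  TensorType<T>::set_dim(out, dim);
  UNPROTECT(1);
  return out;
}

#define DISPATCH_T(x, expr_double, expr_float) \
  (is_float_tensor(x) ? (expr_float) : (expr_double))

#endif
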