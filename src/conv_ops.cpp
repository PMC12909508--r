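// Memory-movement kernels for the convolution engine: im2col/col2im and
// column gather/scatter-add on channel-major matrices.  All heavy
// arithmetic stays in BLAS; these routines only rearrange memory, which
// R-level subscripting does an order of magnitude too slowly.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// patch[(o*Cin)..(o*Cin+Cin-1), k] = xp[, cols(k, o)]
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& xp, const IntegerMatrix& cols) {
  const int Cin = xp.nrow();
  const int K = cols.nrow();
  const int nk = cols.ncol();
  NumericMatrix patch((R_xlen_t)Cin * nk, K);
  const double* xpp = &xp[0];
  double* pp = &patch[0];
  for (int k = 0; k < K; ++k) {
    double* dst = pp + (size_t)k * Cin * nk;
    for (int o = 0; o < nk; ++o) {
      const double* src = xpp + (size_t)(cols(k, o) - 1) * Cin;
      std::memcpy(dst + (size_t)o * Cin, src, (size_t)Cin * sizeof(double));
    }
  }
  return patch;
}

// dxp[, cols(k, o)] += dpatch[(o*Cin)..(o*Cin+Cin-1), k]; in place.
// [[Rcpp::export]]
void cpp_col2im_add(NumericMatrix dxp, const IntegerMatrix& cols,
                    const NumericMatrix& dpatch) {
  const int Cin = dxp.nrow();
  const int K = cols.nrow();
  const int nk = cols.ncol();
  double* dxpp = &dxp[0];
  const double* dp = &dpatch[0];
  for (int k = 0; k < K; ++k) {
    const double* src = dp + (size_t)k * Cin * nk;
    for (int o = 0; o < nk; ++o) {
      double* dst = dxpp + (size_t)(cols(k, o) - 1) * Cin;
      const double* s = src + (size_t)o * Cin;
      for (int c = 0; c < Cin; ++c) dst[c] += s[c];
    }
  }
}

// out = x[, cols]
// [[Rcpp::export]]
NumericMatrix cpp_gather_cols(const NumericMatrix& x,
                              const IntegerVector& cols) {
  const int C = x.nrow();
  const int K = cols.size();
  NumericMatrix out(C, K);
  const double* xpp = &x[0];
  double* op = &out[0];
  for (int k = 0; k < K; ++k)
    std::memcpy(op + (size_t)k * C, xpp + (size_t)(cols[k] - 1) * C,
                (size_t)C * sizeof(double));
  return out;
}

// dst[, cols] += src; in place.
// [[Rcpp::export]]
void cpp_scatter_add_cols(NumericMatrix dst, const IntegerVector& cols,
                          const NumericMatrix& src) {
  const int C = dst.nrow();
  const int K = cols.size();
  double* dp = &dst[0];
  const double* sp = &src[0];
  for (int k = 0; k < K; ++k) {
    double* d = dp + (size_t)(cols[k] - 1) * C;
    const double* s = sp + (size_t)k * C;
    for (int c = 0; c < C; ++c) d[c] += s[c];
  }
}
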