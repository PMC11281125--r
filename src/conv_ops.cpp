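// Hot kernels of the CPU convolution engine: im2col / col2im for stride-1
// 'same' convolutions on [N, H, W, C] column-major arrays. Column blocks are
// ordered kernel-row-major, channel-minor, matching the R-side weight layout.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// xp: padded array [N, Hp, Wp, C]; output (N*H*W) x (k*k*C)
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xp, int k, int H, int W) {
  IntegerVector d = xp.attr("dim");
  const int N = d[0], Hp = d[1], Wp = d[2], C = d[3];
  const size_t plane = (size_t)N * Hp;
  NumericMatrix P((R_xlen_t)N * H * W, (R_xlen_t)k * k * C);
  const double* x = xp.begin();
  double* p = P.begin();
  const size_t nrow = (size_t)N * H * W;
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      for (int c = 0; c < C; ++c) {
        const size_t col = (size_t)C * (a * k + b) + c;
        double* dst0 = p + col * nrow;
        const double* src0 = x + (size_t)c * plane * Wp;
        for (int j = 0; j < W; ++j) {
          const double* src = src0 + (size_t)(j + b) * plane + (size_t)a * N;
          double* dst = dst0 + (size_t)j * H * N;
          std::memcpy(dst, src, (size_t)N * H * sizeof(double));
        }
      }
    }
  }
  return P;
}

// Scatter-add of dP (N*H*W) x (k*k*C) back into a padded gradient array
// [N, Hp, Wp, C]; inverse of im2col_cpp.
// [[Rcpp::export]]
NumericVector col2im_add_cpp(NumericMatrix dP, int N, int Hp, int Wp, int C,
                             int k, int H, int W) {
  NumericVector out((R_xlen_t)N * Hp * Wp * C);
  out.attr("dim") = IntegerVector::create(N, Hp, Wp, C);
  const size_t plane = (size_t)N * Hp;
  const size_t nrow = (size_t)N * H * W;
  const double* p = dP.begin();
  double* x = out.begin();
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      for (int c = 0; c < C; ++c) {
        const size_t col = (size_t)C * (a * k + b) + c;
        const double* src0 = p + col * nrow;
        double* dst0 = x + (size_t)c * plane * Wp;
        for (int j = 0; j < W; ++j) {
          double* dst = dst0 + (size_t)(j + b) * plane + (size_t)a * N;
          const double* src = src0 + (size_t)j * H * N;
          const size_t len = (size_t)N * H;
          for (size_t t = 0; t < len; ++t) dst[t] += src[t];
        }
      }
    }
  }
  return out;
}
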