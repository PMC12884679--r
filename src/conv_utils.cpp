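// Hot loops of the convolution layers: im2col / col2im with implicit
// zero padding and dilation.  Layout matches the R side: feature maps are
// (h, w, c) arrays in column-major order; the column matrix has one row
// per output pixel (row-fastest) and blocks of `cin` columns per kernel
// offset, offsets ordered row-offset-fastest.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int h, int w, int cin,
                         int k, int r) {
  const int pad = r * (k - 1) / 2;
  NumericMatrix col(h * w, cin * k * k);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int block = i + j * k;
      for (int ci = 0; ci < cin; ++ci) {
        const int out_c = block * cin + ci;
        double *dst = &col(0, out_c);
        const double *src = &x[ci * h * w];
        for (int b = 0; b < w; ++b) {
          const int sb = b + j * r - pad;
          if (sb < 0 || sb >= w) continue;
          for (int a = 0; a < h; ++a) {
            const int sa = a + i * r - pad;
            if (sa < 0 || sa >= h) continue;
            dst[a + b * h] = src[sa + sb * h];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int h, int w, int cin,
                         int k, int r) {
  const int pad = r * (k - 1) / 2;
  NumericVector dx(h * w * cin);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int block = i + j * k;
      for (int ci = 0; ci < cin; ++ci) {
        const int in_c = block * cin + ci;
        const double *src = &dcol(0, in_c);
        double *dst = &dx[ci * h * w];
        for (int b = 0; b < w; ++b) {
          const int sb = b + j * r - pad;
          if (sb < 0 || sb >= w) continue;
          for (int a = 0; a < h; ++a) {
            const int sa = a + i * r - pad;
            if (sa < 0 || sa >= h) continue;
            dst[sa + sb * h] += src[a + b * h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(h, w, cin);
  return dx;
}
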