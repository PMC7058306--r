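#include <Rcpp.h>
using namespace Rcpp;

// Image batches are column-major arrays of dim (H, W, C, N).
// im2col unrolls k x k receptive fields into a (k*k*C) x (Ho*Wo*N) matrix so
// that a convolution becomes a single BLAS matrix product; col2im is its
// adjoint (scatter-add), which is exactly the gradient pass back to the input.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int K = k * k * C;
  const long L = (long)Ho * Wo * N;
  NumericMatrix out(K, L);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long l = ho + (long)Ho * wo + (long)Ho * Wo * n;
        double* col = op + l * K;
        for (int c = 0; c < C; ++c) {
          const double* plane = xp + (long)H * W * (c + (long)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride + kh - pad;
              const int r = kh + k * kw + k * k * c;
              col[r] = (h >= 0 && h < H && w >= 0 && w < W)
                         ? plane[h + (long)H * w]
                         : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int K = k * k * C;
  NumericVector dx((long)H * W * C * N);
  double* dp = dx.begin();
  const double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long l = ho + (long)Ho * wo + (long)Ho * Wo * n;
        const double* col = cp + l * K;
        for (int c = 0; c < C; ++c) {
          double* plane = dp + (long)H * W * (c + (long)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              plane[h + (long)H * w] += col[kh + k * kw + k * k * c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
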