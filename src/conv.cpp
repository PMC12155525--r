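#include <Rcpp.h>
using namespace Rcpp;

// im2col / col2im kernels for 'same' k x k convolutions on [H, W, C]
// column-major feature maps. Column layout of the patch matrix matches the
// weight layout used by the R layers: column (o * C + c) holds channel c at
// kernel tap o, with taps ordered dx-major then dy (o = dx * k + dy).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  int n = H * W;
  NumericMatrix out(n, k * k * C);
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy) {
      int o = dx * k + dy;
      for (int c = 0; c < C; ++c) {
        double* col = &out(0, o * C + c);
        const double* src = &x[c * n];
        for (int w = 0; w < W; ++w) {
          int sw = w + dx - p;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, p - dy);
          int h1 = std::min(H, H + p - dy);
          const double* s = src + sw * H + (h0 + dy - p);
          double* d = col + w * H + h0;
          for (int h = h0; h < h1; ++h) *d++ = *s++;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  int n = H * W;
  NumericVector dx(n * C);
  for (int dxo = 0; dxo < k; ++dxo) {
    for (int dy = 0; dy < k; ++dy) {
      int o = dxo * k + dy;
      for (int c = 0; c < C; ++c) {
        const double* col = &dcol(0, o * C + c);
        double* dst = &dx[c * n];
        for (int w = 0; w < W; ++w) {
          int sw = w + dxo - p;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, p - dy);
          int h1 = std::min(H, H + p - dy);
          const double* s = col + w * H + h0;
          double* d = dst + sw * H + (h0 + dy - p);
          for (int h = h0; h < h1; ++h) *d++ += *s++;
        }
      }
    }
  }
  return dx;
}
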