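#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// im2col for channel-first tensors (C, H, W, B): returns the
// (C*k*k) x (oh*ow*B) matrix of a stride-1, k x k convolution with
// symmetric zero padding `pad`. Row index = c + C*(ki + k*kj); column
// index = i + oh*(j + ow*b). The channel dimension is contiguous in both
// source and destination, so the inner copy is a memcpy of C doubles.
// [[Rcpp::export]]
NumericMatrix cs_im2col(NumericVector x, IntegerVector dims, int k, int pad) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int oh = H + 2 * pad - k + 1, ow = W + 2 * pad - k + 1;
  const int R = C * k * k;
  NumericMatrix out(R, oh * ow * B);
  const double *xs = x.begin();
  double *os = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double *col = os + (std::size_t)((b * ow + j) * oh + i) * R;
        for (int kj = 0; kj < k; ++kj) {
          const int w = j + kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            const int h = i + ki - pad;
            double *dst = col + C * (ki + k * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double *src = xs + (std::size_t)((b * W + w) * H + h) * C;
              std::memcpy(dst, src, C * sizeof(double));
            } else {
              std::memset(dst, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add gradient of nearest-neighbour upsampling: accumulates the
// (C, th, tw, B) gradient into the (C, H, W, B) source grid via the
// 1-based row/column source indices used in the forward pass.
// [[Rcpp::export]]
NumericVector cs_upsample_bwd(NumericVector dy, IntegerVector dydims,
                              IntegerVector ridx, IntegerVector cidx,
                              int H, int W) {
  const int C = dydims[0], th = dydims[1], tw = dydims[2], B = dydims[3];
  NumericVector out((std::size_t)C * H * W * B);
  const double *g = dy.begin();
  double *os = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < tw; ++j) {
      const int w = cidx[j] - 1;
      for (int i = 0; i < th; ++i) {
        const int h = ridx[i] - 1;
        double *dst = os + (std::size_t)((b * W + w) * H + h) * C;
        const double *src = g + (std::size_t)((b * tw + j) * th + i) * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, B);
  return out;
}
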