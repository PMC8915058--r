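#include <Rcpp.h>
using namespace Rcpp;

// Linear filtering (correlation) with replicate (clamp-to-edge) borders.
// out(r,c) = sum_{i,j} ker(i,j) * img(r + i - ar, c + j - ac), coordinates
// clamped to the raster.  Symmetric kernels make correlation == convolution;
// derivative kernels on the R side are built for correlation semantics.
// [[Rcpp::export]]
NumericMatrix cpp_filter2(const NumericMatrix &img, const NumericMatrix &ker) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = ker.nrow(), kw = ker.ncol();
  const int ar = kh / 2, ac = kw / 2;

  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kw; ++j) {
        int cc = c + j - ac;
        if (cc < 0) cc = 0; else if (cc >= W) cc = W - 1;
        for (int i = 0; i < kh; ++i) {
          int rr = r + i - ar;
          if (rr < 0) rr = 0; else if (rr >= H) rr = H - 1;
          acc += ker(i, j) * img(rr, cc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}
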