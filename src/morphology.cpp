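#include <Rcpp.h>
using namespace Rcpp;

// Flat (binary-footprint) grayscale erosion / dilation with replicate borders.
// The anchor is the central pixel; R-side validation guarantees odd dimensions
// and a true anchor.  Footprints used by the pipeline (disk, square) are
// symmetric, so erosion/dilation share one window convention.
static NumericMatrix morph_minmax(const NumericMatrix &img,
                                  const LogicalMatrix &fp,
                                  const bool take_max) {
  const int H = img.nrow(), W = img.ncol();
  const int ar = fp.nrow() / 2, ac = fp.ncol() / 2;

  std::vector<int> dr, dc;
  for (int j = 0; j < fp.ncol(); ++j)
    for (int i = 0; i < fp.nrow(); ++i)
      if (fp(i, j)) {
        dr.push_back(i - ar);
        dc.push_back(j - ac);
      }
  const int K = (int)dr.size();

  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double v = take_max ? R_NegInf : R_PosInf;
      for (int k = 0; k < K; ++k) {
        int rr = r + dr[k];
        int cc = c + dc[k];
        if (rr < 0) rr = 0; else if (rr >= H) rr = H - 1;
        if (cc < 0) cc = 0; else if (cc >= W) cc = W - 1;
        const double x = img(rr, cc);
        if (take_max ? (x > v) : (x < v)) v = x;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode(const NumericMatrix &img, const LogicalMatrix &fp) {
  return morph_minmax(img, fp, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate(const NumericMatrix &img, const LogicalMatrix &fp) {
  return morph_minmax(img, fp, true);
}
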