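#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Seeded region growing with an adaptive (running region mean) acceptance
// test.  A candidate neighbor is tested once, against the region mean at the
// moment it is first reached (FIFO order), which makes growth deterministic.
// Growth stops when the frontier is empty or the region holds max_pixels.
// [[Rcpp::export]]
List cpp_region_grow(const NumericMatrix &img,
                     const int seed_r, const int seed_c,
                     const double tol, const int connectivity,
                     const int max_pixels) {
  const int H = img.nrow(), W = img.ncol();
  LogicalMatrix mask(H, W);
  std::vector<char> visited((size_t)H * W, 0);

  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  std::queue<std::pair<int, int> > q;
  double sum = img(seed_r, seed_c);
  int n = 1;
  mask(seed_r, seed_c) = true;
  visited[(size_t)seed_c * H + seed_r] = 1;
  q.push(std::make_pair(seed_r, seed_c));

  while (!q.empty() && n < max_pixels) {
    const std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < nn && n < max_pixels; ++k) {
      const int rr = p.first + dr8[k];
      const int cc = p.second + dc8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const size_t idx = (size_t)cc * H + rr;
      if (visited[idx]) continue;
      visited[idx] = 1;
      if (std::fabs(img(rr, cc) - sum / n) <= tol) {
        mask(rr, cc) = true;
        sum += img(rr, cc);
        ++n;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return List::create(_["mask"] = mask, _["size"] = n,
                      _["mean"] = sum / n);
}
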