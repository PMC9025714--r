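#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Edge-seeded flood fill. img is an h*w*3 integer array (column-major,
// index = y + h*x + h*w*c). metric: 1 = Euclidean, 2 = Chebyshev.
// floating = true compares candidate to the marking neighbor (floating
// range); false compares to the border seed the region grew from.
// Strict "<" against max_distance throughout.

static inline double pix_dist(const int *r, const int *g, const int *b,
                              int p, int q, int metric) {
  double dr = r[p] - r[q], dg = g[p] - g[q], db = b[p] - b[q];
  if (metric == 2) {
    double m = std::fabs(dr);
    if (std::fabs(dg) > m) m = std::fabs(dg);
    if (std::fabs(db) > m) m = std::fabs(db);
    return m;
  }
  return std::sqrt(dr * dr + dg * dg + db * db);
}

// [[Rcpp::export]]
LogicalMatrix flood_mask_cpp(IntegerVector img, int h, int w,
                             double max_distance, int connectivity,
                             int metric, bool floating) {
  const int n = h * w;
  const int *r = img.begin();
  const int *g = r + n;
  const int *b = g + n;

  std::vector<char> marked(n, 0);
  std::vector<int> seed(n, -1); // origin border pixel, for fixed range
  std::vector<int> queue;
  queue.reserve(n);

  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (y == 0 || y == h - 1 || x == 0 || x == w - 1) {
        int p = y + h * x;
        marked[p] = 1;
        seed[p] = p;
        queue.push_back(p);
      }

  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  for (size_t head = 0; head < queue.size(); ++head) {
    int p = queue[head];
    int py = p % h, px = p / h;
    int ref = floating ? p : seed[p];
    for (int k = 0; k < nn; ++k) {
      int qy = py + dy8[k], qx = px + dx8[k];
      if (qy < 0 || qy >= h || qx < 0 || qx >= w) continue;
      int q = qy + h * qx;
      if (marked[q]) continue;
      if (pix_dist(r, g, b, ref, q, metric) < max_distance) {
        marked[q] = 1;
        seed[q] = seed[p];
        queue.push_back(q);
      }
    }
  }

  LogicalMatrix out(h, w);
  for (int i = 0; i < n; ++i) out[i] = marked[i] ? TRUE : FALSE;
  return out;
}
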