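#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

// Circular Hough accumulator by annulus stamping.
//
// votes(a, b, R) counts the edge pixels whose Euclidean distance to the
// integer center (a, b) rounds to R. Each edge pixel therefore votes for
// every center lying on the rasterized annulus [R - 0.5, R + 0.5) around
// it; the annulus offsets are precomputed once per radius. Ties at exactly
// R +/- 0.5 cannot occur for integer coordinates ((2R+1)^2/4 is never an
// integer), so the counting definition is unambiguous.
//
// ex, ey: 0-based edge pixel coordinates (x along width, y along height).
// Returns an integer array with dim (height, width, n_radii).
// [[Rcpp::export]]
IntegerVector hough_votes_cpp(IntegerVector ex, IntegerVector ey,
                              int width, int height, int rmin, int rmax) {
  if (rmin < 1 || rmax < rmin)
    stop("radius range must satisfy 1 <= rmin <= rmax");
  const int nr = rmax - rmin + 1;
  IntegerVector acc((R_xlen_t)width * height * nr, 0);
  int* a = INTEGER(acc);

  std::vector< std::vector< std::pair<int, int> > > offs(nr);
  for (int ri = 0; ri < nr; ++ri) {
    const int R = rmin + ri;
    const double lo2 = (R - 0.5) * (R - 0.5);
    const double hi2 = (R + 0.5) * (R + 0.5);
    for (int dx = -R; dx <= R; ++dx) {
      const double rem_hi = hi2 - (double)dx * dx;
      if (rem_hi <= 0) continue;
      const double rem_lo = lo2 - (double)dx * dx;
      const int dy_max = (int)std::floor(std::sqrt(rem_hi));
      const int dy_min = rem_lo > 0 ? (int)std::ceil(std::sqrt(rem_lo)) : 0;
      for (int dy = dy_min; dy <= dy_max; ++dy) {
        const double d2 = (double)dx * dx + (double)dy * dy;
        if (d2 < lo2 || d2 >= hi2) continue;
        offs[ri].push_back(std::make_pair(dx, dy));
        if (dy != 0) offs[ri].push_back(std::make_pair(dx, -dy));
      }
    }
  }

  const int n = ex.size();
  const R_xlen_t plane = (R_xlen_t)width * height;
  for (int i = 0; i < n; ++i) {
    const int x = ex[i], y = ey[i];
    for (int ri = 0; ri < nr; ++ri) {
      const R_xlen_t base = (R_xlen_t)ri * plane;
      const std::vector< std::pair<int, int> >& ov = offs[ri];
      for (size_t k = 0; k < ov.size(); ++k) {
        const int cx = x + ov[k].first;
        const int cy = y + ov[k].second;
        if (cx < 0 || cx >= width || cy < 0 || cy >= height) continue;
        a[base + (R_xlen_t)cx * height + cy] += 1;
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(height, width, nr);
  return acc;
}
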