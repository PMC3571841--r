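#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circle membership is "rounded Euclidean distance equals r":
// d in [r - 1/2, r + 1/2), i.e. 4*d2 >= (2r-1)^2 and 4*d2 < (2r+1)^2,
// evaluated in exact integer arithmetic.

static inline void dx_bounds(long long A, long long B, int &dxlo, int &dxhi,
                             bool &any) {
  // smallest/largest dx >= 0 with 4*dx^2 in [A, B)
  if (B <= 0) { any = false; return; }
  dxhi = (int)std::floor(std::sqrt((double)B) / 2.0) + 1;
  while (dxhi > 0 && 4LL * dxhi * dxhi >= B) --dxhi;
  if (A <= 0) {
    dxlo = 0;
  } else {
    dxlo = (int)std::ceil(std::sqrt((double)A) / 2.0) - 1;
    if (dxlo < 0) dxlo = 0;
    while (4LL * dxlo * dxlo < A) ++dxlo;
  }
  any = dxlo <= dxhi;
}

// [[Rcpp::export]]
List cpp_hough_circle(LogicalMatrix mask, IntegerVector radii) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> px, py;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) { px.push_back(j); py.push_back(i); }
  if (px.empty()) stop("mask contains no object pixels");

  IntegerVector rads = clone(radii).sort();
  int best_score = -1, best_x = 0, best_y = 0, best_r = 0;
  IntegerMatrix acc(nr, nc);

  int prev_r = -1;
  for (int ri = 0; ri < rads.size(); ++ri) {
    const int r = rads[ri];
    if (r < 1) stop("radii must be >= 1");
    if (r == prev_r) continue;
    prev_r = r;
    std::fill(acc.begin(), acc.end(), 0);
    const long long m1 = (2LL * r - 1) * (2LL * r - 1);
    const long long p1 = (2LL * r + 1) * (2LL * r + 1);
    for (size_t k = 0; k < px.size(); ++k) {
      const int x0 = px[k], y0 = py[k];
      const int dylo = std::max(-r, -y0), dyhi = std::min(r, nr - 1 - y0);
      for (int dy = dylo; dy <= dyhi; ++dy) {
        const long long dy4 = 4LL * dy * dy;
        int dxlo, dxhi; bool any;
        dx_bounds(m1 - dy4, p1 - dy4, dxlo, dxhi, any);
        if (!any) continue;
        const int yy = y0 + dy;
        for (int dx = dxlo; dx <= dxhi; ++dx) {
          int xr = x0 + dx;
          if (xr < nc) ++acc(yy, xr);
          if (dx > 0) {
            int xl = x0 - dx;
            if (xl >= 0) ++acc(yy, xl);
          }
        }
      }
    }
    // scan row-major (rows outer, columns inner); strict > keeps the first
    // maximum, which implements the smallest-r then row-major tie-break
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        if (acc(i, j) > best_score) {
          best_score = acc(i, j); best_x = j; best_y = i; best_r = r;
        }
  }
  return List::create(_["x0"] = best_x, _["y0"] = best_y,
                      _["r"] = best_r, _["score"] = best_score);
}

// [[Rcpp::export]]
IntegerMatrix cpp_hough_accumulator(LogicalMatrix mask, int r) {
  // full accumulator for one radius (diagnostics / tests)
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix acc(nr, nc);
  const long long m1 = (2LL * r - 1) * (2LL * r - 1);
  const long long p1 = (2LL * r + 1) * (2LL * r + 1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      const int dylo = std::max(-r, -i), dyhi = std::min(r, nr - 1 - i);
      for (int dy = dylo; dy <= dyhi; ++dy) {
        const long long dy4 = 4LL * dy * dy;
        int dxlo, dxhi; bool any;
        dx_bounds(m1 - dy4, p1 - dy4, dxlo, dxhi, any);
        if (!any) continue;
        for (int dx = dxlo; dx <= dxhi; ++dx) {
          int xr = j + dx;
          if (xr < nc) ++acc(i + dy, xr);
          if (dx > 0 && j - dx >= 0) ++acc(i + dy, j - dx);
        }
      }
    }
  return acc;
}
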