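#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Even-odd point-in-polygon with inclusive boundary: a point lying on an
// edge (distance < tol) counts as inside. Polygon vertices are in continuous
// grid coordinates; closure is implicit.
static bool pointInPoly(double px, double py, const NumericMatrix& P,
                        double tol) {
  int n = P.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = P(i, 0), yi = P(i, 1);
    double xj = P(j, 0), yj = P(j, 1);
    double dx = xj - xi, dy = yj - yi;
    double len = std::sqrt(dx * dx + dy * dy);
    double cross = dx * (py - yi) - (px - xi) * dy;
    if (len > 0.0 && std::fabs(cross) <= tol * len &&
        px >= std::min(xi, xj) - tol && px <= std::max(xi, xj) + tol &&
        py >= std::min(yi, yj) - tol && py <= std::max(yi, yj) + tol)
      return true;  // on boundary
    if ((yi > py) != (yj > py)) {
      double xint = xi + (py - yi) * dx / dy;
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// Fill a set of polygons onto an nx x ny grid whose voxel centers sit at
// integer coordinates 0..nx-1 / 0..ny-1. Each polygon is filled with the
// even-odd rule; polygons are OR-combined (union across polygons).
// [[Rcpp::export(name = ".fillPolygonsGrid")]]
IntegerMatrix fillPolygonsGrid(List polys, int nx, int ny) {
  IntegerMatrix out(nx, ny);
  const double tol = 1e-9;
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix P = polys[p];
    if (P.nrow() < 3) continue;
    double xmin = P(0, 0), xmax = P(0, 0), ymin = P(0, 1), ymax = P(0, 1);
    for (int i = 1; i < P.nrow(); ++i) {
      xmin = std::min(xmin, P(i, 0)); xmax = std::max(xmax, P(i, 0));
      ymin = std::min(ymin, P(i, 1)); ymax = std::max(ymax, P(i, 1));
    }
    int x0 = std::max(0, (int)std::ceil(xmin - tol));
    int x1 = std::min(nx - 1, (int)std::floor(xmax + tol));
    int y0 = std::max(0, (int)std::ceil(ymin - tol));
    int y1 = std::min(ny - 1, (int)std::floor(ymax + tol));
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix)
        if (!out(ix, iy) && pointInPoly((double)ix, (double)iy, P, tol))
          out(ix, iy) = 1;
  }
  return out;
}
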