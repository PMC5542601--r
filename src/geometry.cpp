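#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Even-odd (ray casting) point-in-polygon test. `poly` is an open ring
// (first vertex not repeated). Points within `boundary_tol` of an edge are
// counted as inside when boundary = TRUE.
static bool point_on_ring(double px, double py, const double* xs, const double* ys,
                          int m, double tol) {
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double ax = xs[i], ay = ys[i], bx = xs[j], by = ys[j];
    double dx = bx - ax, dy = by - ay;
    double L2 = dx * dx + dy * dy;
    double t = 0.0;
    if (L2 > 0.0) {
      t = ((px - ax) * dx + (py - ay) * dy) / L2;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
    }
    double qx = ax + t * dx - px, qy = ay + t * dy - py;
    if (qx * qx + qy * qy <= tol * tol) return true;
  }
  return false;
}

static bool point_in_ring(double px, double py, const double* xs, const double* ys, int m) {
  bool inside = false;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    if (((ys[i] > py) != (ys[j] > py)) &&
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export(rng = false)]]
LogicalVector points_in_polygon_cpp(NumericMatrix pts, NumericMatrix poly,
                                    bool boundary, double boundary_tol) {
  int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  if (m < 3) return out;
  std::vector<double> xs(m), ys(m);
  for (int i = 0; i < m; ++i) { xs[i] = poly(i, 0); ys[i] = poly(i, 1); }
  double xmin = xs[0], xmax = xs[0], ymin = ys[0], ymax = ys[0];
  for (int i = 1; i < m; ++i) {
    xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
    ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
  }
  double pad = boundary ? boundary_tol : 0.0;
  for (int k = 0; k < n; ++k) {
    double px = pts(k, 0), py = pts(k, 1);
    if (px < xmin - pad || px > xmax + pad || py < ymin - pad || py > ymax + pad) {
      out[k] = false;
      continue;
    }
    bool ins = point_in_ring(px, py, xs.data(), ys.data(), m);
    if (!ins && boundary) ins = point_on_ring(px, py, xs.data(), ys.data(), m, boundary_tol);
    out[k] = ins;
  }
  return out;
}
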