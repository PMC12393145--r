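#include <Rcpp.h>
using namespace Rcpp;

// Signed side of point p relative to directed edge a->b (>0 = left).
static inline double side(double ax, double ay, double bx, double by,
                          double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// Sutherland-Hodgman clipping of a simple polygon against a CONVEX
// clipper given in counter-clockwise order.  Returns the clipped
// polygon's vertices (possibly 0 rows when the intersection is empty).
// [[Rcpp::export(".sh_clip")]]
NumericMatrix sh_clip(NumericMatrix subject, NumericMatrix clipper) {
  int ns = subject.nrow(), nc = clipper.nrow();
  std::vector<double> sx, sy;
  sx.reserve(ns + 8);
  sy.reserve(ns + 8);
  for (int i = 0; i < ns; ++i) {
    sx.push_back(subject(i, 0));
    sy.push_back(subject(i, 1));
  }
  for (int e = 0; e < nc && !sx.empty(); ++e) {
    double ax = clipper(e, 0), ay = clipper(e, 1);
    double bx = clipper((e + 1) % nc, 0), by = clipper((e + 1) % nc, 1);
    int n = (int)sx.size();
    std::vector<double> ox, oy;
    ox.reserve(n + 4);
    oy.reserve(n + 4);
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double cx = sx[i], cy = sy[i], dx = sx[j], dy = sy[j];
      double sc = side(ax, ay, bx, by, cx, cy);
      double sd = side(ax, ay, bx, by, dx, dy);
      bool cin = sc >= 0.0, din = sd >= 0.0;
      if (cin) {
        ox.push_back(cx);
        oy.push_back(cy);
      }
      if (cin != din) {
        double t = sc / (sc - sd);
        ox.push_back(cx + t * (dx - cx));
        oy.push_back(cy + t * (dy - cy));
      }
    }
    sx.swap(ox);
    sy.swap(oy);
  }
  NumericMatrix out((int)sx.size(), 2);
  for (int i = 0; i < (int)sx.size(); ++i) {
    out(i, 0) = sx[i];
    out(i, 1) = sy[i];
  }
  return out;
}

// Shoelace signed area (positive for counter-clockwise vertex order).
// [[Rcpp::export(".poly_area_signed")]]
double poly_area_signed(NumericMatrix poly) {
  int n = poly.nrow();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += poly(i, 0) * poly(j, 1) - poly(j, 0) * poly(i, 1);
  }
  return 0.5 * a;
}
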