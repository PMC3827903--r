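#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// In-place excavation kernels. `h` is modified directly (callers pass a
// uniquely-referenced copy); `pristine` is read-only. Coordinates in um,
// pixel centers at (col - 0.5) * ps, (row - 0.5) * ps.

// Lower heights inside a rotated ellipse to pristine - depth.
// [[Rcpp::export(name = ".stamp_ellipse_cpp")]]
int stamp_ellipse_cpp(NumericMatrix h, NumericMatrix pristine,
                      double cx, double cy, double a, double b,
                      double theta, double depth, double ps) {
  const int nr = h.nrow(), nc = h.ncol();
  const double rad = std::max(a, b) + ps;
  int c0 = std::max(0, (int)std::floor((cx - rad) / ps));
  int c1 = std::min(nc - 1, (int)std::ceil((cx + rad) / ps));
  int r0 = std::max(0, (int)std::floor((cy - rad) / ps));
  int r1 = std::min(nr - 1, (int)std::ceil((cy + rad) / ps));
  const double ct = std::cos(theta), st = std::sin(theta);
  int n = 0;
  for (int c = c0; c <= c1; ++c) {
    const double x = (c + 0.5) * ps - cx;
    for (int r = r0; r <= r1; ++r) {
      const double y = (r + 0.5) * ps - cy;
      const double u = (x * ct + y * st) / a;
      const double v = (-x * st + y * ct) / b;
      if (u * u + v * v <= 1.0) {
        const double tgt = pristine(r, c) - depth;
        if (tgt < h(r, c)) h(r, c) = tgt;
        ++n;
      }
    }
  }
  return n;
}

// One trail cycle: stadium band (full depth) from (x0,y0) to (x1,y1) of
// half-width `halfw`, rear cap at full depth, front cap linearly ramped
// from full depth at the segment end to zero at the cap rim.
// [[Rcpp::export(name = ".stamp_cycle_cpp")]]
int stamp_cycle_cpp(NumericMatrix h, NumericMatrix pristine,
                    double x0, double y0, double x1, double y1,
                    double halfw, double depth, double ps) {
  const int nr = h.nrow(), nc = h.ncol();
  const double s = std::sqrt((x1 - x0) * (x1 - x0) + (y1 - y0) * (y1 - y0));
  const double ux = (x1 - x0) / s, uy = (y1 - y0) / s;
  const double xmin = std::min(x0, x1) - halfw - ps,
               xmax = std::max(x0, x1) + halfw + ps;
  const double ymin = std::min(y0, y1) - halfw - ps,
               ymax = std::max(y0, y1) + halfw + ps;
  int c0 = std::max(0, (int)std::floor(xmin / ps));
  int c1 = std::min(nc - 1, (int)std::ceil(xmax / ps));
  int r0 = std::max(0, (int)std::floor(ymin / ps));
  int r1 = std::min(nr - 1, (int)std::ceil(ymax / ps));
  int n = 0;
  for (int c = c0; c <= c1; ++c) {
    const double px = (c + 0.5) * ps;
    for (int r = r0; r <= r1; ++r) {
      const double py = (r + 0.5) * ps;
      const double t = (px - x0) * ux + (py - y0) * uy;
      double frac = 0.0;
      if (t < 0.0) {
        const double rr = std::hypot(px - x0, py - y0);
        if (rr <= halfw) frac = 1.0;
      } else if (t <= s) {
        const double dperp = std::fabs(-(px - x0) * uy + (py - y0) * ux);
        if (dperp <= halfw) frac = 1.0;
      } else {
        const double rr = std::hypot(px - x1, py - y1);
        if (rr <= halfw) frac = 1.0 - rr / halfw;
      }
      if (frac > 0.0) {
        const double tgt = pristine(r, c) - depth * frac;
        if (tgt < h(r, c)) h(r, c) = tgt;
        ++n;
      }
    }
  }
  return n;
}

// Excavation mask: (pristine - final) > threshold, without allocating the
// full difference matrix in R.
// [[Rcpp::export(name = ".excavation_mask_cpp")]]
LogicalMatrix excavation_mask_cpp(NumericMatrix pristine, NumericMatrix final_h,
                                  double threshold) {
  const int nr = pristine.nrow(), nc = pristine.ncol();
  LogicalMatrix mask(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      mask(r, c) = (pristine(r, c) - final_h(r, c)) > threshold;
  return mask;
}
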