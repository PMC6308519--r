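#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact ray/pixel intersection lengths (Siddon-style parametric traversal)
// for every (angle, detector bin) ray of a fan-flat or parallel geometry.
//
// Grid: n x n pixels of size h (mm), centred on the origin; row r (1-based)
// runs down the image (+y up), column c runs right (+x). Pixel (r, c) is
// flattened column-major: i = (c - 1) * n + r.
// Rays are indexed angle-major: j = (a - 1) * n_det + k.
//
// Fan geometry: the source sits at -sod * (cos t, sin t); the flat detector
// row lies at distance sid from the source, bins spaced det_pitch mm along
// the detector axis u = (-sin t, cos t). Parallel geometry: rays travel
// along (cos t, sin t) with lateral offsets of det_pitch * sod / sid mm
// (the demagnified pitch) at the isocentre.
// [[Rcpp::export]]
List cpp_siddon_trace(int n, double h, int n_det, NumericVector angles_rad,
                      bool fan, double sod, double sid, double det_pitch_mm) {
  const double L = n * h, xmin = -L / 2.0, ymin = -L / 2.0;
  const int n_angles = angles_rad.size();
  std::vector<int> pix, ray;
  std::vector<double> len;
  pix.reserve((size_t)n_angles * n_det * n);
  ray.reserve((size_t)n_angles * n_det * n);
  len.reserve((size_t)n_angles * n_det * n);

  const double pitch_iso = det_pitch_mm * sod / sid;
  const double inf = std::numeric_limits<double>::infinity();

  for (int a = 0; a < n_angles; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int k = 0; k < n_det; ++k) {
      const double off = (k + 1 - (n_det + 1) / 2.0);
      double ax, ay, ex, ey;  // point on ray, unit direction
      if (fan) {
        const double sx = -sod * ct, sy = -sod * st;
        const double t_det = off * det_pitch_mm;
        const double dx = sx + sid * ct - t_det * st;
        const double dy = sy + sid * st + t_det * ct;
        double vx = dx - sx, vy = dy - sy;
        const double vn = std::sqrt(vx * vx + vy * vy);
        ax = sx; ay = sy; ex = vx / vn; ey = vy / vn;
      } else {
        const double t_off = off * pitch_iso;
        ax = -t_off * st; ay = t_off * ct;
        ex = ct; ey = st;
      }
      // clip the infinite line to the grid box (slab method)
      double t0 = -inf, t1 = inf;
      bool miss = false;
      if (std::fabs(ex) < 1e-14) {
        if (ax <= xmin || ax >= xmin + L) miss = true;
      } else {
        double ta = (xmin - ax) / ex, tb = (xmin + L - ax) / ex;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
      if (std::fabs(ey) < 1e-14) {
        if (ay <= ymin || ay >= ymin + L) miss = true;
      } else {
        double ta = (ymin - ay) / ey, tb = (ymin + L - ay) / ey;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
      if (miss || t1 - t0 <= 1e-12) continue;  // all-zero row: ray misses grid

      const int j = a * n_det + k + 1;
      // incremental traversal
      double t = t0;
      const double mid = t0 + 1e-9 * (t1 - t0);
      int ix = (int)std::floor((ax + mid * ex - xmin) / h);
      int iy = (int)std::floor((ay + mid * ey - ymin) / h);
      if (ix < 0) ix = 0; if (ix > n - 1) ix = n - 1;
      if (iy < 0) iy = 0; if (iy > n - 1) iy = n - 1;
      const int stepx = ex > 0 ? 1 : -1, stepy = ey > 0 ? 1 : -1;
      const double dtx = std::fabs(ex) > 1e-14 ? h / std::fabs(ex) : inf;
      const double dty = std::fabs(ey) > 1e-14 ? h / std::fabs(ey) : inf;
      double tx = inf, ty = inf;
      if (std::fabs(ex) > 1e-14) {
        const double xb = xmin + (ix + (stepx > 0 ? 1 : 0)) * h;
        tx = (xb - ax) / ex;
      }
      if (std::fabs(ey) > 1e-14) {
        const double yb = ymin + (iy + (stepy > 0 ? 1 : 0)) * h;
        ty = (yb - ay) / ey;
      }
      while (t < t1 - 1e-12) {
        double tn = std::min(std::min(tx, ty), t1);
        const double seg = tn - t;
        if (seg > 1e-12) {
          const int r = n - iy;       // 1-based row (y up -> row down)
          const int c = ix + 1;       // 1-based column
          pix.push_back((c - 1) * n + r);
          ray.push_back(j);
          len.push_back(seg);
        }
        if (tx <= ty && tx <= t1) { ix += stepx; tx += dtx; }
        else if (ty < tx && ty <= t1) { iy += stepy; ty += dty; }
        t = tn;
        if (ix < 0 || ix > n - 1 || iy < 0 || iy > n - 1) break;
      }
    }
  }
  return List::create(_["i"] = wrap(ray), _["j"] = wrap(pix), _["x"] = wrap(len));
}
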