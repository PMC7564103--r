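#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parametric entry point of segment p0 + t*(p1-p0), t in [0,1], into the
// closed axis-aligned square [xmin,xmax] x [ymin,ymax] (slab clipping).
// Returns entry parameter t in [0,1], or -1 if the segment misses the square.
static double segment_aabb_entry(double x0, double y0, double x1, double y1,
                                 double xmin, double xmax,
                                 double ymin, double ymax) {
  double tmin = 0.0, tmax = 1.0;
  double d, lo, hi, t1, t2;

  d = x1 - x0;
  if (d == 0.0) {
    if (x0 < xmin || x0 > xmax) return -1.0;
  } else {
    lo = (xmin - x0) / d; hi = (xmax - x0) / d;
    t1 = lo < hi ? lo : hi; t2 = lo < hi ? hi : lo;
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
    if (tmin > tmax) return -1.0;
  }

  d = y1 - y0;
  if (d == 0.0) {
    if (y0 < ymin || y0 > ymax) return -1.0;
  } else {
    lo = (ymin - y0) / d; hi = (ymax - y0) / d;
    t1 = lo < hi ? lo : hi; t2 = lo < hi ? hi : lo;
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
    if (tmin > tmax) return -1.0;
  }

  return tmin;
}

// First trap hit by the segment (x0,y0)->(x1,y1); physical first contact
// (smallest entry parameter) wins ties. traps: columns xmin,xmax,ymin,ymax.
// Returns 1-based trap index or 0; writes entry t into *t_out when hit.
static int first_hit(double x0, double y0, double x1, double y1,
                     const NumericMatrix &traps, double *t_out) {
  int best = 0;
  double tbest = 2.0;
  for (int j = 0; j < traps.nrow(); ++j) {
    double t = segment_aabb_entry(x0, y0, x1, y1,
                                  traps(j, 0), traps(j, 1),
                                  traps(j, 2), traps(j, 3));
    if (t >= 0.0 && t < tbest) { tbest = t; best = j + 1; }
  }
  if (best > 0) *t_out = tbest;
  return best;
}

// [[Rcpp::export]]
IntegerVector segment_trap_hit_cpp(NumericVector x0, NumericVector y0,
                                   NumericVector x1, NumericVector y1,
                                   NumericMatrix traps) {
  int n = x0.size();
  IntegerVector out(n);
  double t;
  for (int i = 0; i < n; ++i)
    out[i] = first_hit(x0[i], y0[i], x1[i], y1[i], traps, &t);
  return out;
}

// Correlated random walk with absorbing square traps in unbounded 2-D space.
// Movers start at (x,y) with an initial uniform heading, take the first step
// on that heading, then add a Normal(0, csd_deg^2) turn before each later
// step. Captured movers freeze at the segment's entry point into the trap.
// Uses R's RNG stream: draws are mover-major within each step, so a given
// set.seed() fully determines the run.
// [[Rcpp::export]]
List crw_run_cpp(NumericVector start_x, NumericVector start_y,
                 int n_steps, double step_length, double csd_deg,
                 NumericMatrix traps, bool segment_mode) {
  RNGScope scope;
  const int n = start_x.size();
  const double deg2rad = M_PI / 180.0;

  NumericVector x = clone(start_x), y = clone(start_y);
  NumericVector heading(n);             // radians
  IntegerVector captured_by(n, 0);      // 0 = free, else 1-based trap index
  IntegerVector capture_step(n, NA_INTEGER);

  for (int i = 0; i < n; ++i)
    heading[i] = R::runif(0.0, 360.0) * deg2rad;

  // loose bounding box around all traps, padded by one step, so far-away
  // movers skip the trap loop entirely
  double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf;
  for (int j = 0; j < traps.nrow(); ++j) {
    bx0 = std::min(bx0, traps(j, 0)); bx1 = std::max(bx1, traps(j, 1));
    by0 = std::min(by0, traps(j, 2)); by1 = std::max(by1, traps(j, 3));
  }
  bx0 -= step_length; bx1 += step_length;
  by0 -= step_length; by1 += step_length;

  int n_free = n;
  for (int s = 1; s <= n_steps && n_free > 0; ++s) {
    for (int i = 0; i < n; ++i) {
      if (captured_by[i] != 0) continue;
      if (s > 1)
        heading[i] += R::rnorm(0.0, csd_deg) * deg2rad;
      double nx = x[i] + step_length * std::cos(heading[i]);
      double ny = y[i] + step_length * std::sin(heading[i]);

      bool near = !(x[i] < bx0 && nx < bx0) && !(x[i] > bx1 && nx > bx1) &&
                  !(y[i] < by0 && ny < by0) && !(y[i] > by1 && ny > by1);
      if (near) {
        int hit = 0;
        double t = 0.0;
        if (segment_mode) {
          hit = first_hit(x[i], y[i], nx, ny, traps, &t);
        } else {
          for (int j = 0; j < traps.nrow(); ++j) {
            if (nx >= traps(j, 0) && nx <= traps(j, 1) &&
                ny >= traps(j, 2) && ny <= traps(j, 3)) { hit = j + 1; t = 1.0; break; }
          }
        }
        if (hit != 0) {
          captured_by[i] = hit;
          capture_step[i] = s;
          x[i] = x[i] + t * (nx - x[i]);
          y[i] = y[i] + t * (ny - y[i]);
          --n_free;
          continue;
        }
      }
      x[i] = nx;
      y[i] = ny;
    }
  }

  return List::create(_["x"] = x, _["y"] = y,
                      _["heading_deg"] = heading / deg2rad,
                      _["captured_by"] = captured_by,
                      _["capture_step"] = capture_step);
}
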