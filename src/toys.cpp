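#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// One-dimensional overdamped walkers used as independent oracle substrates
// for the FFS and equilibrium machinery.
//
// pot_id 0: symmetric double well  V(x) = h (x^2 - 1)^2
// pot_id 1: radial dimer coordinate V(r) = -eps (1 - (r/rc)^2)^2 for r < rc,
//           plus the 3D entropic term -2 kT ln(r), reflecting walls at
//           [rmin, rmax]. This is the distance coordinate of a pair of
//           particles with an isotropic short-range attraction.
// ---------------------------------------------------------------------------

struct Walker {
  int pot_id;
  double h, tilt, eps, rc, rmin, rmax, kT, D, dt;

  double force(double x) const {
    if (pot_id == 0) {
      return -4.0 * h * x * (x * x - 1.0) - tilt;
    } else {
      double f = 0.0;
      if (x < rc) {
        double u = x / rc;
        double m = 1.0 - u * u;
        // dV/dr = 4 eps u m / rc  (V = -eps m^2), force = -dV/dr
        f -= 4.0 * eps * u * m / rc;
      }
      f += 2.0 * kT / x; // -d/dr (-2 kT ln r)
      return f;
    }
  }

  double step(double x) const {
    x += (D / kT) * force(x) * dt + std::sqrt(2.0 * D * dt) * norm_rand();
    if (pot_id == 1) {
      if (x < rmin) x = 2.0 * rmin - x;
      if (x > rmax) x = 2.0 * rmax - x;
    }
    return x;
  }

  static Walker from_list(List p) {
    Walker w;
    w.pot_id = as<int>(p["pot_id"]);
    w.h = p["h"]; w.tilt = p["tilt"]; w.eps = p["eps"]; w.rc = p["rc"];
    w.rmin = p["rmin"]; w.rmax = p["rmax"];
    w.kT = p["kT"]; w.D = p["D"]; w.dt = p["dt"];
    return w;
  }
};

// [[Rcpp::export]]
List cpp_walker_run(double x0, List wpar, int nsteps, int stride) {
  Walker w = Walker::from_list(wpar);
  double x = x0;
  std::vector<double> path;
  for (int n = 1; n <= nsteps; ++n) {
    x = w.step(x);
    if (stride > 0 && n % stride == 0) path.push_back(x);
  }
  return List::create(Named("x") = x,
                      Named("path") = NumericVector(path.begin(), path.end()));
}

// [[Rcpp::export]]
List cpp_walker_until(double x0, List wpar, double lam_up, double lam_down,
                      int max_steps) {
  Walker w = Walker::from_list(wpar);
  double x = x0;
  int hit = 0, steps = 0;
  if (x >= lam_up) hit = 1;
  else if (x <= lam_down) hit = -1;
  while (hit == 0 && steps < max_steps) {
    x = w.step(x); ++steps;
    if (x >= lam_up) hit = 1;
    else if (x <= lam_down) hit = -1;
  }
  return List::create(Named("x") = x, Named("hit") = hit, Named("steps") = steps);
}

// Effective-positive-flux run confined (in its time normalization) to the
// A-attached phase: steps after reaching lam_target and before returning to
// the basin are not counted, so spontaneous full transitions do not
// contaminate the flux denominator.
// [[Rcpp::export]]
List cpp_walker_flux(double x0, List wpar, double lam0, double lam_basin,
                     double lam_target, int target_crossings, int max_steps) {
  Walker w = Walker::from_list(wpar);
  double x = x0;
  std::vector<double> crossings;
  bool armed = (x <= lam_basin);
  bool inA = true;
  long steps = 0, stepsA = 0;
  while (steps < max_steps && (int)crossings.size() < target_crossings) {
    x = w.step(x); ++steps;
    if (inA) {
      ++stepsA;
      if (x >= lam_target) { inA = false; armed = false; }
      else if (armed && x >= lam0) { crossings.push_back(x); armed = false; }
      else if (!armed && x <= lam_basin) armed = true;
    } else if (x <= lam_basin) {
      inA = true; armed = true;
    }
  }
  return List::create(
    Named("states") = NumericVector(crossings.begin(), crossings.end()),
    Named("steps") = (double)steps, Named("steps_in_A") = (double)stepsA,
    Named("n_crossings") = (int)crossings.size());
}

// Brute-force rate: long unbiased run, transitions counted per unit time
// attached to basin A ("effective positive flux" convention, the same
// normalization the FFS estimate uses).
// [[Rcpp::export]]
List cpp_walker_brute_rate(double x0, List wpar, double lam_basin,
                           double lam_target, double basin_b, long nsteps,
                           int direction) {
  Walker w = Walker::from_list(wpar);
  double x = x0;
  long stepsA = 0, ntrans = 0;
  bool inA = true;
  for (long n = 0; n < nsteps; ++n) {
    x = w.step(x);
    bool at_target = (direction > 0) ? (x >= lam_target) : (x <= lam_target);
    bool back_in_A = (direction > 0) ? (x <= basin_b) : (x >= basin_b);
    if (inA) {
      ++stepsA;
      if (at_target) { ++ntrans; inA = false; }
    } else if (back_in_A) {
      inA = true;
    }
  }
  return List::create(Named("n_transitions") = (double)ntrans,
                      Named("time_in_A") = (double)stepsA * w.dt,
                      Named("x") = x);
}

// Mean occupancy of x < xsplit over a long run (toy equilibrium oracle check)
// [[Rcpp::export]]
List cpp_walker_occupancy(double x0, List wpar, double xsplit, long nsteps,
                          long burn) {
  Walker w = Walker::from_list(wpar);
  double x = x0;
  long cnt = 0, tot = 0;
  for (long n = 0; n < nsteps; ++n) {
    x = w.step(x);
    if (n >= burn) { ++tot; if (x < xsplit) ++cnt; }
  }
  return List::create(Named("occupancy") = (double)cnt / (double)tot,
                      Named("x") = x);
}
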