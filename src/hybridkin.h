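#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// ---------------------------------------------------------------------------
// Small 3-vector
// ---------------------------------------------------------------------------
struct Vec {
  double x, y, z;
};
inline Vec vec3(double x, double y, double z) { return {x, y, z}; }
inline Vec operator+(const Vec& a, const Vec& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec operator-(const Vec& a, const Vec& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec operator*(const Vec& a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline Vec& operator+=(Vec& a, const Vec& b) { a.x += b.x; a.y += b.y; a.z += b.z; return a; }
inline Vec& operator-=(Vec& a, const Vec& b) { a.x -= b.x; a.y -= b.y; a.z -= b.z; return a; }
inline double dot(const Vec& a, const Vec& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec cross(const Vec& a, const Vec& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const Vec& a) { return std::sqrt(dot(a, a)); }

// Rotate v by angle theta about unit axis u (Rodrigues)
inline Vec rotate(const Vec& v, const Vec& u, double theta) {
  double c = std::cos(theta), s = std::sin(theta);
  return v * c + cross(u, v) * s + u * (dot(u, v) * (1.0 - c));
}

// ---------------------------------------------------------------------------
// Scalar potential primitives (all C1; radial/angular factors compact support)
// ---------------------------------------------------------------------------

// Quartic radial well: V = -eps (1-u^2)^2, u = (r-r0)/w, support |u|<1
inline double vbump(double r, double eps, double r0, double w, double* dVdr) {
  double u = (r - r0) / w;
  if (u <= -1.0 || u >= 1.0) { *dVdr = 0.0; return 0.0; }
  double m = 1.0 - u * u;
  *dVdr = 4.0 * eps * u * m / w;
  return -eps * m * m;
}

// Quartic angular modulation: g = (1-q^2)^2, q = (c-c0)/w, support |q|<1
inline double abump(double c, double c0, double w, double* dgdc) {
  double q = (c - c0) / w;
  if (q <= -1.0 || q >= 1.0) { *dgdc = 0.0; return 0.0; }
  double m = 1.0 - q * q;
  *dgdc = -4.0 * q * m / w;
  return m * m;
}

// WCA repulsion (C1 at cutoff 2^(1/6) sigma)
inline double wca(double r, double eps, double sig, double* dVdr) {
  const double rc = sig * 1.122462048309373;
  if (r >= rc) { *dVdr = 0.0; return 0.0; }
  double ir = sig / r;
  double s6 = ir * ir * ir; s6 *= s6;
  double s12 = s6 * s6;
  *dVdr = 4.0 * eps * (-12.0 * s12 + 6.0 * s6) / r;
  return 4.0 * eps * (s12 - s6) + eps;
}

// FENE spring with linear continuation outside |s| > 0.995 (keeps V finite and
// C1 so that rejected MC moves and the blow-up guard behave sensibly)
inline double fene(double r, double eps, double r0, double delta, double* dVdr) {
  double s = (r - r0) / delta;
  const double smax = 0.995;
  if (s > smax || s < -smax) {
    double sc = (s > 0) ? smax : -smax;
    double m = 1.0 - sc * sc;
    double V0 = -0.5 * eps * std::log(m);
    double slope = eps * sc / (delta * m);
    *dVdr = slope;
    return V0 + slope * ((r - r0) - sc * delta);
  }
  double m = 1.0 - s * s;
  *dVdr = eps * s / (delta * m);
  return -0.5 * eps * std::log(m);
}

// ---------------------------------------------------------------------------
// Model parameters (filled from the packaged key-value tables via R)
// ---------------------------------------------------------------------------
struct Model {
  // interaction-site offsets along a1 (body frame)
  double pos_back, pos_stack, pos_hb;
  // backbone FENE
  double fene_eps, fene_r0, fene_delta;
  // excluded volume
  double exc_eps, sig_bb, sig_bs, sig_ss, sig_bonded;
  // hydrogen bonding
  double hb_r0, hb_wr, hb_w1, hb_w2;
  double hb_eps[4][4];
  // stacking (strength linear in kT)
  double st_r0, st_wr, st_w1, st_cref2, st_w2, st_eta, st_alpha;
  double st_fac[4][4];
  // cross-stacking (interstrand)
  double cx_eps, cx_r0, cx_wr, cx_w1;
  // coaxial stacking (optional model-family term)
  bool coax_on;
  double coax_eps, coax_r0, coax_wr, coax_w1;
  bool native_only;

  static Model from_list(Rcpp::List p) {
    Model m;
    m.pos_back  = p["pos_back"];  m.pos_stack = p["pos_stack"]; m.pos_hb = p["pos_hb"];
    m.fene_eps  = p["fene_eps"];  m.fene_r0   = p["fene_r0"];   m.fene_delta = p["fene_delta"];
    m.exc_eps   = p["exc_eps"];   m.sig_bb    = p["sig_bb"];    m.sig_bs = p["sig_bs"];
    m.sig_ss    = p["sig_ss"];    m.sig_bonded = p["sig_bonded"];
    m.hb_r0     = p["hb_r0"];     m.hb_wr     = p["hb_wr"];
    m.hb_w1     = p["hb_w1"];     m.hb_w2     = p["hb_w2"];
    m.st_r0     = p["st_r0"];     m.st_wr     = p["st_wr"];     m.st_w1 = p["st_w1"];
    m.st_cref2  = p["st_cref2"];  m.st_w2     = p["st_w2"];
    m.st_eta    = p["st_eta"];    m.st_alpha  = p["st_alpha"];
    m.cx_eps    = p["cx_eps"];    m.cx_r0     = p["cx_r0"];     m.cx_wr = p["cx_wr"];
    m.cx_w1     = p["cx_w1"];
    m.coax_on   = Rcpp::as<bool>(p["coax_on"]);
    m.coax_eps  = p["coax_eps"];  m.coax_r0   = p["coax_r0"];
    m.coax_wr   = p["coax_wr"];   m.coax_w1   = p["coax_w1"];
    m.native_only = Rcpp::as<bool>(p["native_only"]);
    Rcpp::NumericMatrix hb = p["hb_eps_mat"];
    Rcpp::NumericMatrix sf = p["st_fac_mat"];
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) { m.hb_eps[a][b] = hb(a, b); m.st_fac[a][b] = sf(a, b); }
    return m;
  }
};

// Staged order-parameter definition used by FFS runners
struct OPSpec {
  double thr;        // hydrogen-bond pairing threshold (< 0)
  double d_contact;  // first-interface site separation
  double d_basin;    // unbound-basin site separation (> d_contact)
  bool native_count; // count only native pairs in the staged values
};

// ---------------------------------------------------------------------------
// System state + energy kernel
// ---------------------------------------------------------------------------
struct Sys {
  int N;
  std::vector<Vec> com, a1, a3, vel, ang; // ang: angular momentum (inertia = 1)
  std::vector<int> base, strand, pos, nat;
  double box;
  double kT; // thermal energy entering the T-dependent stacking strength
  Model m;

  // accumulators
  double E[6]; // backbone, hb, stacking, cross, coax, excluded
  std::vector<Vec> dcom, da1, da3;

  Vec mi(const Vec& d) const {
    return {d.x - box * std::nearbyint(d.x / box),
            d.y - box * std::nearbyint(d.y / box),
            d.z - box * std::nearbyint(d.z / box)};
  }

  void alloc() {
    dcom.assign(N, {0, 0, 0});
    da1.assign(N, {0, 0, 0});
    da3.assign(N, {0, 0, 0});
  }

  bool bonded(int i, int j) const {
    return strand[i] == strand[j] && std::abs(pos[i] - pos[j]) == 1;
  }
  bool hb_allowed(int i, int j) const {
    if (base[i] + base[j] != 3) return false;
    if (m.native_only && nat[i] != j) return false;
    // intra-strand pairing with a loop shorter than 3 nucleotides cannot
    // close physically; the rigid-body geometry alone would permit it
    if (strand[i] == strand[j] && std::abs(pos[i] - pos[j]) < 4) return false;
    return true;
  }

  void add_radial(int i, int j, double la, double lb, double V, double dVdr,
                  const Vec& rhat, bool grad, int term) {
    E[term] += V;
    if (grad && dVdr != 0.0) {
      Vec G = rhat * dVdr;
      dcom[i] -= G; dcom[j] += G;
      da1[i] -= G * la; da1[j] += G * lb;
    }
  }

  // generic radial-only site-site term
  void site_radial(int i, int j, const Vec& d, double la, double lb, int kind,
                   double eps, double sig_or_r0, double extra, bool grad, int term) {
    Vec rv = d + a1[j] * lb - a1[i] * la;
    double r = norm(rv);
    if (r < 1e-12) return;
    double dV = 0.0, V = 0.0;
    if (kind == 0) V = wca(r, eps, sig_or_r0, &dV);
    else V = fene(r, eps, sig_or_r0, extra, &dV);
    if (V == 0.0 && dV == 0.0) return;
    add_radial(i, j, la, lb, V, dV, rv * (1.0 / r), grad, term);
  }

  void hb_pair(int i, int j, const Vec& d, bool grad) {
    double eps = m.hb_eps[base[i]][base[j]];
    if (eps == 0.0) return;
    double l = m.pos_hb;
    Vec rv = d + a1[j] * l - a1[i] * l;
    double r = norm(rv);
    if (r < 1e-12) return;
    double df;
    double f = vbump(r, eps, m.hb_r0, m.hb_wr, &df);
    if (f == 0.0) return;
    Vec rhat = rv * (1.0 / r);
    double dg1, dg2, dg3;
    double c1 = dot(a3[i], a3[j]);
    double g1 = abump(c1, -1.0, m.hb_w1, &dg1);
    if (g1 == 0.0) return;
    double c2 = dot(rhat, a1[i]);
    double g2 = abump(c2, 1.0, m.hb_w2, &dg2);
    if (g2 == 0.0) return;
    double c3 = -dot(rhat, a1[j]);
    double g3 = abump(c3, 1.0, m.hb_w2, &dg3);
    if (g3 == 0.0) return;
    E[1] += f * g1 * g2 * g3;
    if (grad) {
      Vec dc2dr = (a1[i] - rhat * c2) * (1.0 / r);
      Vec dc3dr = (a1[j] * (-1.0) - rhat * c3) * (1.0 / r);
      Vec Gr = rhat * (df * g1 * g2 * g3)
             + dc2dr * (f * g1 * dg2 * g3)
             + dc3dr * (f * g1 * g2 * dg3);
      dcom[i] -= Gr; dcom[j] += Gr;
      da1[i] += rhat * (f * g1 * dg2 * g3) - Gr * l;
      da1[j] += rhat * (-(f * g1 * g2 * dg3)) + Gr * l;
      da3[i] += a3[j] * (f * dg1 * g2 * g3);
      da3[j] += a3[i] * (f * dg1 * g2 * g3);
    }
  }

  // p5 is the 5' member of the bonded pair; d = mi(com[p3] - com[p5])
  void stack_pair(int p5, int p3, const Vec& d, bool grad) {
    double l = m.pos_stack;
    Vec rv = d + a1[p3] * l - a1[p5] * l;
    double r = norm(rv);
    if (r < 1e-12) return;
    double eps = (m.st_eta + m.st_alpha * kT) * m.st_fac[base[p5]][base[p3]];
    double df;
    double f = vbump(r, eps, m.st_r0, m.st_wr, &df);
    if (f == 0.0) return;
    Vec rhat = rv * (1.0 / r);
    double dg1, dhu, dhv;
    double c1 = dot(a3[p5], a3[p3]);
    double g1 = abump(c1, 1.0, m.st_w1, &dg1);
    if (g1 == 0.0) return;
    double u = dot(rhat, a3[p5]);
    double hu = abump(u * u, m.st_cref2, m.st_w2, &dhu);
    if (hu == 0.0) return;
    double v = dot(rhat, a3[p3]);
    double hv = abump(v * v, m.st_cref2, m.st_w2, &dhv);
    if (hv == 0.0) return;
    E[2] += f * g1 * hu * hv;
    if (grad) {
      Vec dudr = (a3[p5] - rhat * u) * (1.0 / r);
      Vec dvdr = (a3[p3] - rhat * v) * (1.0 / r);
      Vec Gr = rhat * (df * g1 * hu * hv)
             + dudr * (f * g1 * (dhu * 2.0 * u) * hv)
             + dvdr * (f * g1 * hu * (dhv * 2.0 * v));
      dcom[p5] -= Gr; dcom[p3] += Gr;
      da1[p5] -= Gr * l; da1[p3] += Gr * l;
      da3[p5] += a3[p3] * (f * dg1 * hu * hv) + rhat * (f * g1 * (dhu * 2.0 * u) * hv);
      da3[p3] += a3[p5] * (f * dg1 * hu * hv) + rhat * (f * g1 * hu * (dhv * 2.0 * v));
    }
  }

  // antiparallel-normal interstrand stacking term (cross-stacking), or the
  // aligned-normal coaxial variant when c0 = +1
  void normstack_pair(int i, int j, const Vec& d, double eps, double r0, double wr,
                      double w1, double c0, bool grad, int term) {
    double l = m.pos_stack;
    Vec rv = d + a1[j] * l - a1[i] * l;
    double r = norm(rv);
    if (r < 1e-12) return;
    double df;
    double f = vbump(r, eps, r0, wr, &df);
    if (f == 0.0) return;
    Vec rhat = rv * (1.0 / r);
    double dg;
    double c = dot(a3[i], a3[j]);
    double g = abump(c, c0, w1, &dg);
    if (g == 0.0) return;
    E[term] += f * g;
    if (grad) {
      Vec Gr = rhat * (df * g);
      dcom[i] -= Gr; dcom[j] += Gr;
      da1[i] -= Gr * l; da1[j] += Gr * l;
      da3[i] += a3[j] * (f * dg);
      da3[j] += a3[i] * (f * dg);
    }
  }

  void do_pair(int i, int j, bool grad) {
    Vec d = mi(com[j] - com[i]);
    bool bd = bonded(i, j);
    if (!bd && dot(d, d) > 4.0) return; // beyond every cutoff + site offsets
    if (bd) {
      int p5 = (pos[i] < pos[j]) ? i : j;
      int p3 = (p5 == i) ? j : i;
      Vec d53 = mi(com[p3] - com[p5]);
      site_radial(p5, p3, d53, m.pos_back, m.pos_back, 1,
                  m.fene_eps, m.fene_r0, m.fene_delta, grad, 0);
      stack_pair(p5, p3, d53, grad);
      site_radial(p5, p3, d53, m.pos_hb, m.pos_hb, 0,
                  m.exc_eps, m.sig_bonded, 0, grad, 5);
    } else {
      site_radial(i, j, d, m.pos_back, m.pos_back, 0, m.exc_eps, m.sig_bb, 0, grad, 5);
      site_radial(i, j, d, m.pos_back, m.pos_hb, 0, m.exc_eps, m.sig_bs, 0, grad, 5);
      site_radial(i, j, d, m.pos_hb, m.pos_back, 0, m.exc_eps, m.sig_bs, 0, grad, 5);
      site_radial(i, j, d, m.pos_hb, m.pos_hb, 0, m.exc_eps, m.sig_ss, 0, grad, 5);
      if (hb_allowed(i, j)) hb_pair(i, j, d, grad);
      if (strand[i] != strand[j])
        normstack_pair(i, j, d, m.cx_eps, m.cx_r0, m.cx_wr, m.cx_w1, -1.0, grad, 3);
      if (m.coax_on)
        normstack_pair(i, j, d, m.coax_eps, m.coax_r0, m.coax_wr, m.coax_w1, 1.0, grad, 4);
    }
  }

  void zero() { for (int t = 0; t < 6; ++t) E[t] = 0.0; alloc(); }

  void compute(bool grad) {
    zero();
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        do_pair(i, j, grad);
  }

  double total() const {
    return E[0] + E[1] + E[2] + E[3] + E[4] + E[5];
  }

  // energy of particle k with its environment (for single-particle MC moves)
  double one_energy(int k) {
    zero();
    for (int j = 0; j < N; ++j) if (j != k) do_pair(std::min(j, k), std::max(j, k), false);
    return total();
  }

  double pair_total(int i, int j) {
    zero();
    do_pair(std::min(i, j), std::max(i, j), false);
    return total();
  }

  double hb_energy(int i, int j) {
    if (bonded(i, j) || !hb_allowed(i, j)) return 0.0;
    double e0 = E[1]; E[1] = 0.0;
    Vec d = mi(com[j] - com[i]);
    hb_pair(i, j, d, false);
    double v = E[1];
    E[1] = e0;
    return v;
  }

  // unique interstrand base-pair assignment below threshold (the
  // secondary-structure and order-parameter convention counts pairs
  // between strands; intra-strand bonding, where allowed, contributes to
  // the energy but not to n); optionally restricted to native pairs.
  // Fills pairs with (i, j, e) triples when requested.
  int count_bp(double thr, bool native_only_count,
               std::vector<std::array<double, 3>>* pairs = nullptr) {
    struct Cand { int i, j; double e; };
    std::vector<Cand> cand;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (strand[i] == strand[j]) continue;
        if (bonded(i, j) || !hb_allowed(i, j)) continue;
        if (native_only_count && nat[i] != j) continue;
        double e = hb_energy(i, j);
        if (e <= thr) cand.push_back({i, j, e});
      }
    std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
      if (a.e != b.e) return a.e < b.e;
      if (a.i != b.i) return a.i < b.i;
      return a.j < b.j;
    });
    std::vector<bool> used(N, false);
    int n = 0;
    for (auto& c : cand) {
      if (used[c.i] || used[c.j]) continue;
      used[c.i] = used[c.j] = true;
      ++n;
      if (pairs) pairs->push_back({(double)c.i, (double)c.j, c.e});
    }
    return n;
  }

  // minimum interstrand site-site distance over backbone and base sites
  double min_interstrand_dist() {
    double best = 1e30;
    const double offs[2] = {m.pos_back, m.pos_hb};
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (strand[i] == strand[j]) continue;
        Vec d = mi(com[j] - com[i]);
        for (double la : offs)
          for (double lb : offs) {
            double r = norm(d + a1[j] * lb - a1[i] * la);
            if (r < best) best = r;
          }
      }
    return best;
  }

  // staged order parameter: 0 = unbound basin, 0.5 = no-man's land,
  // 1 = interstrand contact, 1 + n with n base pairs
  double lambda(const OPSpec& op) {
    int n = count_bp(op.thr, op.native_count);
    if (n > 0) return 1.0 + n;
    double dmin = min_interstrand_dist();
    if (dmin <= op.d_contact) return 1.0;
    if (dmin >= op.d_basin) return 0.0;
    return 0.5;
  }

  void orthonormalize() {
    for (int i = 0; i < N; ++i) {
      double n1 = norm(a1[i]);
      a1[i] = a1[i] * (1.0 / n1);
      a3[i] -= a1[i] * dot(a3[i], a1[i]);
      double n3 = norm(a3[i]);
      a3[i] = a3[i] * (1.0 / n3);
    }
  }
};

// Build a Sys from the standard R-side argument set
inline Sys make_sys(Rcpp::NumericMatrix com, Rcpp::NumericMatrix a1,
                    Rcpp::NumericMatrix a3, Rcpp::NumericMatrix vel,
                    Rcpp::NumericMatrix ang, Rcpp::IntegerVector base,
                    Rcpp::IntegerVector strand, Rcpp::IntegerVector pos,
                    Rcpp::IntegerVector nat, double box, double kT,
                    Rcpp::List par) {
  Sys s;
  s.N = com.nrow();
  s.box = box;
  s.kT = kT;
  s.m = Model::from_list(par);
  s.com.resize(s.N); s.a1.resize(s.N); s.a3.resize(s.N);
  s.vel.resize(s.N); s.ang.resize(s.N);
  s.base.resize(s.N); s.strand.resize(s.N); s.pos.resize(s.N); s.nat.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.com[i] = {com(i, 0), com(i, 1), com(i, 2)};
    s.a1[i] = {a1(i, 0), a1(i, 1), a1(i, 2)};
    s.a3[i] = {a3(i, 0), a3(i, 1), a3(i, 2)};
    s.vel[i] = {vel(i, 0), vel(i, 1), vel(i, 2)};
    s.ang[i] = {ang(i, 0), ang(i, 1), ang(i, 2)};
    s.base[i] = base[i]; s.strand[i] = strand[i]; s.pos[i] = pos[i]; s.nat[i] = nat[i];
  }
  s.alloc();
  return s;
}

inline Rcpp::NumericMatrix to_mat(const std::vector<Vec>& v) {
  Rcpp::NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) { m(i, 0) = v[i].x; m(i, 1) = v[i].y; m(i, 2) = v[i].z; }
  return m;
}

inline Rcpp::List sys_state(const Sys& s) {
  return Rcpp::List::create(
    Rcpp::Named("com") = to_mat(s.com), Rcpp::Named("a1") = to_mat(s.a1),
    Rcpp::Named("a3") = to_mat(s.a3), Rcpp::Named("vel") = to_mat(s.vel),
    Rcpp::Named("ang") = to_mat(s.ang));
}

inline OPSpec op_from_list(Rcpp::List op) {
  OPSpec o;
  o.thr = op["thr"];
  o.d_contact = op["d_contact"];
  o.d_basin = op["d_basin"];
  o.native_count = Rcpp::as<bool>(op["native_count"]);
  return o;
}
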