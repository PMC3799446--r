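#include "hybridkin.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rigid-body Langevin / Brownian propagation.
// Langevin scheme: BAOAB splitting with unit mass and unit isotropic inertia;
// the O-step is the exact Ornstein-Uhlenbeck update, so fluctuation and
// dissipation balance by construction and gamma = 0 reduces to velocity
// Verlet (symplectic, energy conserving).
// Brownian scheme: overdamped Euler-Maruyama in position and orientation.
// ---------------------------------------------------------------------------

struct Thermo {
  int scheme;           // 0 = langevin, 1 = brownian
  double dt, Dt, Dr, gamma_t, gamma_r;
  static Thermo from_list(List t) {
    Thermo h;
    h.scheme = as<int>(t["scheme"]);
    h.dt = t["dt"]; h.Dt = t["Dt"]; h.Dr = t["Dr"];
    h.gamma_t = t["gamma_t"]; h.gamma_r = t["gamma_r"];
    return h;
  }
};

struct Integrator {
  Sys& s;
  Thermo th;
  double kT;
  std::vector<Vec> F, T;
  double epot;

  Integrator(Sys& sys, Thermo t, double kt) : s(sys), th(t), kT(kt) {
    F.resize(s.N); T.resize(s.N);
    eval_forces();
  }

  void eval_forces() {
    s.compute(true);
    epot = s.total();
    double fmax2 = 0.0;
    for (int i = 0; i < s.N; ++i) {
      F[i] = s.dcom[i] * (-1.0);
      T[i] = cross(s.da1[i], s.a1[i]) + cross(s.da3[i], s.a3[i]);
      fmax2 = std::max(fmax2, dot(F[i], F[i]));
    }
    if (!std::isfinite(epot) || !std::isfinite(fmax2))
      stop("numerical blow-up: non-finite energy or force");
    // the inertial scheme cannot absorb runaway forces (the overdamped
    // update caps its per-step displacement, so transient core overlaps
    // resolve harmlessly there)
    if (th.scheme == 0 && fmax2 > 1e16)
      stop("numerical blow-up: runaway force in the Langevin integrator");
  }

  void rotate_body(int i, const Vec& w, double dt) {
    double wn = norm(w);
    if (wn < 1e-14) return;
    Vec u = w * (1.0 / wn);
    s.a1[i] = rotate(s.a1[i], u, wn * dt);
    s.a3[i] = rotate(s.a3[i], u, wn * dt);
  }

  void ld_step() {
    double h = th.dt;
    for (int i = 0; i < s.N; ++i) {
      s.vel[i] += F[i] * (0.5 * h);
      s.ang[i] += T[i] * (0.5 * h);
    }
    for (int i = 0; i < s.N; ++i) {
      s.com[i] += s.vel[i] * (0.5 * h);
      rotate_body(i, s.ang[i], 0.5 * h);
    }
    if (th.gamma_t > 0 || th.gamma_r > 0) {
      double c1t = std::exp(-th.gamma_t * h), c2t = std::sqrt((1.0 - c1t * c1t) * kT);
      double c1r = std::exp(-th.gamma_r * h), c2r = std::sqrt((1.0 - c1r * c1r) * kT);
      for (int i = 0; i < s.N; ++i) {
        s.vel[i] = s.vel[i] * c1t + vec3(norm_rand(), norm_rand(), norm_rand()) * c2t;
        s.ang[i] = s.ang[i] * c1r + vec3(norm_rand(), norm_rand(), norm_rand()) * c2r;
      }
    }
    for (int i = 0; i < s.N; ++i) {
      s.com[i] += s.vel[i] * (0.5 * h);
      rotate_body(i, s.ang[i], 0.5 * h);
    }
    s.orthonormalize();
    eval_forces();
    for (int i = 0; i < s.N; ++i) {
      s.vel[i] += F[i] * (0.5 * h);
      s.ang[i] += T[i] * (0.5 * h);
    }
  }

  void bd_step() {
    double h = th.dt;
    double mob_t = th.Dt / kT, mob_r = th.Dr / kT;
    double st = std::sqrt(2.0 * th.Dt * h), sr = std::sqrt(2.0 * th.Dr * h);
    // rare force spikes (steep repulsive cores) overshoot in a plain
    // Euler-Maruyama update; capping the per-step displacement/rotation
    // keeps the scheme stable. The caps sit far above typical noise steps
    // so they clip only pathological moves.
    const double cap_x = 0.1, cap_r = 0.2;
    for (int i = 0; i < s.N; ++i) {
      Vec dx = F[i] * (mob_t * h) + vec3(norm_rand(), norm_rand(), norm_rand()) * st;
      double nx = norm(dx);
      if (nx > cap_x) dx = dx * (cap_x / nx);
      s.com[i] += dx;
      Vec phi = T[i] * (mob_r * h) + vec3(norm_rand(), norm_rand(), norm_rand()) * sr;
      double np = norm(phi);
      if (np > cap_r) phi = phi * (cap_r / np);
      rotate_body(i, phi, 1.0);
    }
    s.orthonormalize();
    eval_forces();
  }

  void step() { if (th.scheme == 0) ld_step(); else bd_step(); }

  double ekin() const {
    double e = 0.0;
    for (int i = 0; i < s.N; ++i)
      e += 0.5 * dot(s.vel[i], s.vel[i]) + 0.5 * dot(s.ang[i], s.ang[i]);
    return e;
  }
};

// [[Rcpp::export]]
List cpp_sim_run(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                 NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                 IntegerVector strand, IntegerVector pos, IntegerVector nat,
                 double box, double kT, List par, List thermo,
                 int nsteps, int stride, bool store_frames) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  Integrator it(s, Thermo::from_list(thermo), kT);
  List frames;
  std::vector<double> e_step, e_pot, e_kin;
  if (stride > 0) {
    e_step.push_back(0); e_pot.push_back(it.epot); e_kin.push_back(it.ekin());
    if (store_frames) frames.push_back(sys_state(s));
  }
  for (int n = 1; n <= nsteps; ++n) {
    it.step();
    if (stride > 0 && n % stride == 0) {
      e_step.push_back(n); e_pot.push_back(it.epot); e_kin.push_back(it.ekin());
      if (store_frames) frames.push_back(sys_state(s));
    }
  }
  NumericMatrix em(e_step.size(), 3);
  for (size_t k = 0; k < e_step.size(); ++k) {
    em(k, 0) = e_step[k]; em(k, 1) = e_pot[k]; em(k, 2) = e_kin[k];
  }
  colnames(em) = CharacterVector::create("step", "epot", "ekin");
  return List::create(Named("state") = sys_state(s), Named("energies") = em,
                      Named("frames") = frames);
}

// Propagate until the staged order parameter reaches lam_up (hit = 1) or
// falls to lam_down (hit = -1); hit = 0 when the step budget runs out.
// [[Rcpp::export]]
List cpp_run_until(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                   NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                   IntegerVector strand, IntegerVector pos, IntegerVector nat,
                   double box, double kT, List par, List thermo, List opspec,
                   double lam_up, double lam_down, int max_steps, int check_every) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  OPSpec op = op_from_list(opspec);
  Integrator it(s, Thermo::from_list(thermo), kT);
  int hit = 0, steps = 0;
  double lam = s.lambda(op);
  if (lam >= lam_up) hit = 1;
  else if (lam <= lam_down) hit = -1;
  while (hit == 0 && steps < max_steps) {
    for (int k = 0; k < check_every && steps < max_steps; ++k) { it.step(); ++steps; }
    lam = s.lambda(op);
    if (lam >= lam_up) hit = 1;
    else if (lam <= lam_down) hit = -1;
  }
  return List::create(Named("state") = sys_state(s), Named("hit") = hit,
                      Named("steps") = steps, Named("lambda") = lam);
}

// Effective-positive-flux measurement: count forward crossings of lam0 from
// the basin (lambda <= lam_basin re-arms the counter) and store the crossing
// states. Time is accumulated only while attached to basin A: steps between
// reaching lam_target and returning to the basin do not enter the flux
// denominator.
// [[Rcpp::export]]
List cpp_flux_run(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                  NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                  IntegerVector strand, IntegerVector pos, IntegerVector nat,
                  double box, double kT, List par, List thermo, List opspec,
                  double lam0, double lam_basin, double lam_target,
                  int target_crossings, int max_steps, int check_every) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  OPSpec op = op_from_list(opspec);
  Integrator it(s, Thermo::from_list(thermo), kT);
  // keep the initial basin state: reaching the target resets the run there
  // (with fresh Maxwell-Boltzmann momenta), since an associated duplex
  // would otherwise trap the basin run for the rest of the budget
  std::vector<Vec> com0 = s.com, a10 = s.a1, a30 = s.a3;
  double mom_sd = std::sqrt(kT);
  List states;
  long steps = 0, stepsA = 0;
  int ncross = 0;
  bool armed = (s.lambda(op) <= lam_basin);
  while (steps < max_steps && ncross < target_crossings) {
    for (int k = 0; k < check_every && steps < max_steps; ++k) { it.step(); ++steps; }
    double lam = s.lambda(op);
    stepsA += check_every;
    if (lam >= lam_target) {
      s.com = com0; s.a1 = a10; s.a3 = a30;
      for (int i = 0; i < s.N; ++i) {
        s.vel[i] = vec3(norm_rand(), norm_rand(), norm_rand()) * mom_sd;
        s.ang[i] = vec3(norm_rand(), norm_rand(), norm_rand()) * mom_sd;
      }
      it.eval_forces();
      armed = true;
    } else if (armed && lam >= lam0) {
      states.push_back(sys_state(s));
      ++ncross;
      armed = false;
    } else if (!armed && lam <= lam_basin) armed = true;
  }
  return List::create(Named("states") = states, Named("steps") = (double)steps,
                      Named("steps_in_A") = (double)stepsA,
                      Named("n_crossings") = ncross);
}

// ---------------------------------------------------------------------------
// Cluster-move Metropolis Monte Carlo with optional umbrella bias over the
// base-pair count n. Single-particle translations/rotations plus rigid moves
// of energetically connected clusters; a cluster move is rejected when the
// move would change the cluster's membership, which keeps the proposal
// symmetric and preserves detailed balance.
// ---------------------------------------------------------------------------

static std::vector<int> build_cluster(Sys& s, int seed, double bond_e) {
  std::vector<int> stack = {seed}, members;
  std::vector<bool> in(s.N, false);
  in[seed] = true;
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    members.push_back(c);
    for (int j = 0; j < s.N; ++j) {
      if (in[j]) continue;
      if (s.bonded(c, j) || s.pair_total(c, j) < bond_e) {
        in[j] = true;
        stack.push_back(j);
      }
    }
  }
  std::sort(members.begin(), members.end());
  return members;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                IntegerVector strand, IntegerVector pos, IntegerVector nat,
                double box, double kT, List par, int nsweeps,
                double sigma_tr, double sigma_rot, double p_cluster,
                double bond_e, NumericVector bias, double thr,
                bool native_count, int store_stride, bool log_moves,
                int max_log) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  int nbins = s.N / 2 + 2;
  std::vector<double> hist(nbins, 0.0);
  auto wght = [&](int n) -> double {
    if (bias.size() == 0) return 1.0;
    int k = std::min(n, (int)bias.size() - 1);
    return bias[k];
  };
  int n_cur = s.count_bp(thr, native_count);
  long acc_single = 0, try_single = 0, acc_cluster = 0, try_cluster = 0;
  std::vector<double> log_dE, log_wr; std::vector<int> log_acc;
  List frames; std::vector<int> frame_n;

  auto metropolis = [&](double dE, double wr) -> bool {
    double p = wr * std::exp(-dE / kT);
    return unif_rand() < p;
  };
  auto gauss_axis = [&]() {
    Vec u = vec3(norm_rand(), norm_rand(), norm_rand());
    double n = norm(u);
    return (n > 1e-12) ? u * (1.0 / n) : vec3(1, 0, 0);
  };

  for (int sw = 1; sw <= nsweeps; ++sw) {
    for (int mv = 0; mv < s.N; ++mv) {
      if (unif_rand() < p_cluster) {
        // ---- rigid cluster move ----
        ++try_cluster;
        int seed = (int)std::floor(unif_rand() * s.N);
        std::vector<int> C = build_cluster(s, seed, bond_e);
        bool trans = (unif_rand() < 0.5);
        Vec shift = vec3(norm_rand(), norm_rand(), norm_rand()) * sigma_tr;
        Vec axis = gauss_axis();
        double angle = norm_rand() * sigma_rot;
        // centroid relative to the seed (min image keeps the cluster compact)
        Vec ref = s.com[seed], cen = vec3(0, 0, 0);
        std::vector<Vec> rel(C.size());
        for (size_t k = 0; k < C.size(); ++k) {
          rel[k] = s.mi(s.com[C[k]] - ref);
          cen += rel[k];
        }
        cen = cen * (1.0 / C.size());
        if ((int)C.size() == s.N) {
          // whole-system move: no energy change, always accepted
          for (size_t k = 0; k < C.size(); ++k) {
            int c = C[k];
            if (trans) s.com[c] += shift;
            else {
              s.com[c] = ref + cen + rotate(rel[k] - cen, axis, angle);
              s.a1[c] = rotate(s.a1[c], axis, angle);
              s.a3[c] = rotate(s.a3[c], axis, angle);
            }
          }
          ++acc_cluster;
          continue;
        }
        std::vector<bool> inC(s.N, false);
        for (int c : C) inC[c] = true;
        double e0 = 0.0;
        for (int c : C)
          for (int o = 0; o < s.N; ++o)
            if (!inC[o]) e0 += s.pair_total(c, o);
        std::vector<Vec> sc(C.size()), s1(C.size()), s3(C.size());
        for (size_t k = 0; k < C.size(); ++k) {
          int c = C[k];
          sc[k] = s.com[c]; s1[k] = s.a1[c]; s3[k] = s.a3[c];
          if (trans) s.com[c] += shift;
          else {
            s.com[c] = ref + cen + rotate(rel[k] - cen, axis, angle);
            s.a1[c] = rotate(s.a1[c], axis, angle);
            s.a3[c] = rotate(s.a3[c], axis, angle);
          }
        }
        double e1 = 0.0;
        for (int c : C)
          for (int o = 0; o < s.N; ++o)
            if (!inC[o]) e1 += s.pair_total(c, o);
        std::vector<int> C2 = build_cluster(s, seed, bond_e);
        int n_new = s.count_bp(thr, native_count);
        bool ok = (C2 == C);
        double dE = e1 - e0;
        double wr = wght(n_new) / wght(n_cur);
        if (log_moves && (int)log_dE.size() < max_log && ok) {
          log_dE.push_back(dE); log_wr.push_back(wr);
        }
        bool accept = ok && metropolis(dE, wr);
        if (log_moves && (int)log_acc.size() < (int)log_dE.size() && ok)
          log_acc.push_back(accept ? 1 : 0);
        if (accept) { n_cur = n_new; ++acc_cluster; }
        else {
          for (size_t k = 0; k < C.size(); ++k) {
            int c = C[k];
            s.com[c] = sc[k]; s.a1[c] = s1[k]; s.a3[c] = s3[k];
          }
        }
      } else {
        // ---- single-particle move ----
        ++try_single;
        int k = (int)std::floor(unif_rand() * s.N);
        double e0 = s.one_energy(k);
        Vec sc = s.com[k], s1 = s.a1[k], s3 = s.a3[k];
        if (unif_rand() < 0.5) {
          s.com[k] += vec3(norm_rand(), norm_rand(), norm_rand()) * sigma_tr;
        } else {
          Vec axis = gauss_axis();
          double angle = norm_rand() * sigma_rot;
          s.a1[k] = rotate(s.a1[k], axis, angle);
          s.a3[k] = rotate(s.a3[k], axis, angle);
        }
        double e1 = s.one_energy(k);
        int n_new = s.count_bp(thr, native_count);
        double dE = e1 - e0;
        double wr = wght(n_new) / wght(n_cur);
        if (log_moves && (int)log_dE.size() < max_log) {
          log_dE.push_back(dE); log_wr.push_back(wr);
        }
        bool accept = metropolis(dE, wr);
        if (log_moves && (int)log_acc.size() < (int)log_dE.size())
          log_acc.push_back(accept ? 1 : 0);
        if (accept) { n_cur = n_new; ++acc_single; }
        else { s.com[k] = sc; s.a1[k] = s1; s.a3[k] = s3; }
      }
    }
    if (n_cur < nbins) hist[n_cur] += 1.0;
    if (store_stride > 0 && sw % store_stride == 0) {
      frames.push_back(sys_state(s));
      frame_n.push_back(n_cur);
    }
  }

  List out = List::create(
    Named("state") = sys_state(s),
    Named("hist") = NumericVector(hist.begin(), hist.end()),
    Named("n_final") = n_cur,
    Named("acc_single") = (double)acc_single / std::max(1L, try_single),
    Named("acc_cluster") = (double)acc_cluster / std::max(1L, try_cluster),
    Named("frames") = frames,
    Named("frame_n") = IntegerVector(frame_n.begin(), frame_n.end()));
  if (log_moves) {
    out["move_log"] = DataFrame::create(
      Named("dE") = NumericVector(log_dE.begin(), log_dE.end()),
      Named("wr") = NumericVector(log_wr.begin(), log_wr.end()),
      Named("accepted") = IntegerVector(log_acc.begin(), log_acc.end()));
  }
  return out;
}
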