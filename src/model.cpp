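#include "hybridkin.h"
using namespace Rcpp;

static NumericVector term_vector(const Sys& s) {
  NumericVector e = NumericVector::create(
    Named("backbone") = s.E[0],
    Named("hydrogen_bonding") = s.E[1],
    Named("stacking") = s.E[2],
    Named("cross_stacking") = s.E[3],
    Named("coaxial_stacking") = s.E[4],
    Named("excluded_volume") = s.E[5]);
  return e;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                IntegerVector strand, IntegerVector pos, IntegerVector nat,
                double box, double kT, List par, bool grad) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  s.compute(grad);
  List out = List::create(Named("terms") = term_vector(s), Named("total") = s.total());
  if (grad) {
    std::vector<Vec> F(s.N), T(s.N);
    for (int i = 0; i < s.N; ++i) {
      F[i] = s.dcom[i] * (-1.0);
      T[i] = cross(s.da1[i], s.a1[i]) + cross(s.da3[i], s.a3[i]);
    }
    out["force"] = to_mat(F);
    out["torque"] = to_mat(T);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pair_energy(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                     NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                     IntegerVector strand, IntegerVector pos, IntegerVector nat,
                     double box, double kT, List par, int i, int j) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  s.zero();
  s.do_pair(std::min(i, j), std::max(i, j), false);
  return List::create(Named("terms") = term_vector(s), Named("total") = s.total());
}

// Unique base-pair assignment below an energy threshold.
// Returns matrix with columns i, j, e (0-based global indices).
// [[Rcpp::export]]
NumericMatrix cpp_base_pairs(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                             NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                             IntegerVector strand, IntegerVector pos, IntegerVector nat,
                             double box, double kT, List par, double thr,
                             bool native_only_count) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  std::vector<std::array<double, 3>> pairs;
  s.count_bp(thr, native_only_count, &pairs);
  NumericMatrix out(pairs.size(), 3);
  for (size_t k = 0; k < pairs.size(); ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = pairs[k][c];
  return out;
}

// Per-bonded-pair stacking energies (columns: i5, i3, e_stack)
// [[Rcpp::export]]
NumericMatrix cpp_stack_energies(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                                 NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                                 IntegerVector strand, IntegerVector pos, IntegerVector nat,
                                 double box, double kT, List par) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  std::vector<std::array<double, 3>> rows;
  for (int i = 0; i < s.N; ++i)
    for (int j = i + 1; j < s.N; ++j) {
      if (!s.bonded(i, j)) continue;
      int p5 = (s.pos[i] < s.pos[j]) ? i : j;
      int p3 = (p5 == i) ? j : i;
      s.zero();
      Vec d = s.mi(s.com[p3] - s.com[p5]);
      s.stack_pair(p5, p3, d, false);
      rows.push_back({(double)p5, (double)p3, s.E[2]});
    }
  NumericMatrix out(rows.size(), 3);
  for (size_t k = 0; k < rows.size(); ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = rows[k][c];
  return out;
}

// [[Rcpp::export]]
double cpp_min_interstrand_dist(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                                NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                                IntegerVector strand, IntegerVector pos, IntegerVector nat,
                                double box, double kT, List par) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  return s.min_interstrand_dist();
}

// [[Rcpp::export]]
double cpp_lambda(NumericMatrix com, NumericMatrix a1, NumericMatrix a3,
                  NumericMatrix vel, NumericMatrix ang, IntegerVector base,
                  IntegerVector strand, IntegerVector pos, IntegerVector nat,
                  double box, double kT, List par, List opspec) {
  Sys s = make_sys(com, a1, a3, vel, ang, base, strand, pos, nat, box, kT, par);
  return s.lambda(op_from_list(opspec));
}
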