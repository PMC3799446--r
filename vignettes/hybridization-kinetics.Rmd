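---
title: "Methods: a coarse-grained model and rare-event toolchain for DNA oligomer hybridization kinetics"
author: "hybridkin"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hybridkin` represents a DNA strand as a chain of rigid bodies, one per
nucleotide. A nucleotide's pose is its centre of mass plus a right-handed
orthonormal frame: `a1` is the base-face direction, `a3` the base-stacking
normal. Three interaction sites are rigid functions of the pose, all on
the `a1` axis: a backbone site at −0.40 length units, a stacking site at
+0.34 and a hydrogen-bonding/repulsion site at +0.40. One simulation
length unit is 0.8518 nm.

The potential is a sum of six terms:

* **Backbone connectivity** — a FENE spring between the backbone sites of
  bonded neighbours (rest length 0.70, range 0.25, strength 4). Outside
  99.5% of its range the potential continues linearly, so badly strained
  starting structures have finite energies and relax instead of
  overflowing.
* **Hydrogen bonding** — between the hydrogen-bonding sites of
  non-neighbour nucleotides whose identities are Watson–Crick
  complementary (A-T or C-G) *only*; all other identity combinations have
  exactly zero strength. Intra-strand pairs with a loop shorter than
  three nucleotides are excluded: a rigid-body geometry alone would let
  (i, i+2) "hairpins" close, which is sterically impossible for DNA, and
  such spurious pairs would contaminate the single-strand ensemble (and,
  before this rule was in place, did contaminate the interface ensembles
  of the rate calculations). The term is a compact-support quartic radial well
  (depth ε, minimum at 0.40, support width 0.30) modulated by three
  quartic angular factors that select antiparallel stacking normals and
  face-to-face alignment of the two bases. In the sequence-averaged
  parameterization ε is 1.07 simulation energy units for both A-T and
  G-C; in the sequence-dependent parameterization ε(A-T) = 0.88 and
  ε(G-C) = 1.26, making G-C pairs more stable.
* **Stacking** — between the stacking sites of bonded neighbours, radial
  well at 0.42 with angular factors favouring aligned normals roughly
  parallel to the site-site vector. Its strength is
  (1.34 + 2.66 kT) · g(b₅)·g(b₃): the linear kT dependence mimics the
  entropic character of stacking, and the per-base factors g (all 1 in
  the averaged variant; 0.90–1.10 in the sequence-dependent one) give
  nearest-neighbour sequence dependence.
* **Cross-stacking** — a weaker interstrand term (depth 0.20, minimum at
  0.63) between stacking sites with antiparallel normals; it stabilizes
  the duplex beyond the hydrogen bonds and gives initial contacts some
  favourable interaction before a full base pair forms.
* **Coaxial stacking** — a member of the model family that can be enabled
  with `set_coaxial()`; the shipped default is off, matching the model
  version used for all the results here.
* **Excluded volume** — WCA (purely repulsive, C1 at its cutoff) between
  backbone-backbone, backbone-base and base-base site pairs of
  non-neighbours, and a small base-base core between neighbours.
  Electrostatics is not explicit: the parameterization corresponds to a
  fixed high-salt condition under which screening justifies folding
  repulsion into a short-ranged excluded volume.

Every term has compact support (or a C1 cutoff), which makes the cutoff
contract exact: beyond the largest term cutoff a pair's energy is
identically zero. All functional forms are C1, and the analytic forces
and body torques are tested against central differences of the energy at
relative tolerance 1e-6, together with Newton's-third-law and
net-torque-zero sums and invariance of the energy under global
translation and rotation.

Why quartic compact-support wells rather than Morse/harmonic forms with
smoothing windows? They make differentiability and the cutoff contract
structural properties instead of things to verify term by term, at the
cost of slightly different well shapes; nothing downstream depends on the
precise shape, only on depths, ranges and the angular selectivity.

The pair loop is direct O(N²). The systems in this study have at most 28
nucleotides, where a Verlet list would cost more than it saves; the code
is structured so a list could be added behind `Sys::compute` if larger
systems were ever needed.

## Units and temperature calibration

Simulation units: length 0.8518 nm, thermal energy kT = T[K] / 1622, so
one energy unit is k_B·1622 K = 3.2232 kcal/mol. The temperature scale is
the model's one calibrated constant: it was fixed, once, so that the
umbrella-sampled free-energy profile of the native-only 14-bp duplex at
300 K descends by ≈1.7 kcal/mol per added base pair (−2.84 kT/bp measured
in the calibration scan). With a single scale factor the model's slope at
340.9 K comes out near −1.1 kcal/mol and its duplex-stability edge sits
somewhat above 340.9 K; the parameterization is *not* fitted to
nearest-neighbour melting thermodynamics, so temperatures should be read
as model temperatures anchored at the 300 K slope, not as quantitative
melting predictions.

# Dynamics

**Langevin.** Rigid-body BAOAB splitting with unit mass and unit
isotropic inertia: half-kick, half-drift (Rodrigues rotation by the
angular velocity), an exact Ornstein–Uhlenbeck velocity/angular-momentum
update, half-drift, half-kick. Fluctuation and dissipation balance by
construction (the OU update is exact), and γ = 0 reduces the scheme to
symplectic velocity Verlet — the suite checks energy drift < 1e-4 over
1e4 steps at dt = 0.0015. Thermostat inputs are diffusion coefficients;
friction is γ = kT/D at the run temperature (at T = 0 an explicit γ must
be given). Defaults D_t = 1, D_r = 3, dt = 0.005 were chosen by the
stability and equipartition tests. Validation: free-particle diffusion
recovers D within 5% (multi-origin MSD fit whose intercept absorbs the
inertial offset) and an interacting 4-nucleotide duplex equilibrates to
kT/2 per degree of freedom within 3%.

**Brownian.** Overdamped Euler–Maruyama in position and orientation, used
for the sequence-dependent campaigns with a larger diffusion coefficient
(D_t = 2, D_r = 6, dt = 2e-4). A per-step displacement cap (0.1 length
units, 0.2 rad) makes rare force spikes from transient core overlaps
harmless; typical steps are far below the cap.

**Accelerated diffusion.** Like any coarse-grained treatment the model's
absolute time scale is not physical, and campaigns additionally run with
`diffusion_scale = 3`. The scale is a recorded run condition:
`relative_rate()` refuses to compare estimates across different
thermostats, boxes, timesteps or diffusion scales, so every headline
quantity is a ratio or probability at matched conditions.

# Equilibrium sampling

**Cluster-move Monte Carlo.** Metropolis sampling with single-nucleotide
translations/rotations (σ = 0.12 / 0.22) mixed with rigid moves of
energetically connected clusters (pair energy < −0.1 defines a bond). A
cluster move that would change the cluster's membership when rebuilt from
its seed is rejected, which keeps the proposal symmetric and detailed
balance exact; whole-system moves are always accepted, so bound duplexes
diffuse without artificial suppression. The acceptance rule is exposed as
`mc_accept_prob()` and audited against the per-move log.

**Umbrella sampling.** Weights w(n) over the base-pair count bias the
chain; the recorded histogram is reweighted by 1/w(n) (an exact identity,
checked on toys where ΔF is known by quadrature). `run_umbrella()`
reports F(n) = −kT ln P(n) offset to min 0, with block-averaged errors
and never-visited n marked unsampled rather than invented. Weights are
adapted by an explore phase (multiplicative update on the last histogram,
log-jump capped at 6 per unit n) followed by consolidation against the
accumulated reweighted estimate, then frozen for production. Profiles of
duplexes exclude the unbound state (its weight is pinned ~1e-9): F(n≥1)
is concentration independent, n = 0 is not.

# Forward flux sampling

Direct FFS over a staged order parameter λ: 0 in the unbound basin
(minimum interstrand site distance > 1.5), 1 at interstrand contact
(≤ 0.8), and 1 + n with n base pairs; the target is the full duplex (or,
for repetitive sequences, a first structure of ≥ 4 base pairs in any
register, measured with the total count — long-lived misaligned
intermediates make a single rate into the full duplex ill-defined for
FFS, so their fates are resolved by separate unbiased runs). The basin
run counts effective positive crossings of the contact interface per unit
basin-attached time; reaching the target resets the run to its initial
state with fresh Maxwell–Boltzmann momenta, since an associated duplex
never dissociates on the run's timescale. Shots start from uniformly
drawn stored crossing states with fresh noise; success is reaching the
next interface before the unbound basin; probabilities use resolved shots
only, with a warning if more than 10% of shots exhaust their budget.
`k = Φ0·Πp_i` carries Poisson/binomial errors and a parametric-bootstrap
CI. The estimator's primary oracle is a 1D double-well walker whose rate
is measured by brute force; the suite checks agreement and
interface-placement invariance at 2σ. Because the interfaces are
(contact, 1 bp, 2 bp, target), the final-stage probability *is* the
commitment probability of the two-base-pair penultimate ensemble.

# Secondary structure and pathway classification

A base pair is an interstrand (i, j) whose hydrogen-bond term is at or
below 15% of the typical full depth (the threshold is exposed); when a
base passes the threshold with two partners the lower-energy pair wins,
ties toward the lower index. The base-pair count n used by the order
parameter and the umbrella bias follows the same interstrand convention:
intra-strand bonding, where allowed, contributes energy but never counts
as a pair. With both strands indexed 0..N−1 from the 5'
end and the native partner of i being N−1−i, a pair's register is
r = j − (N−1−i). The sign convention is fixed by the worked AC/GT
example: the maximal register-(−8) structure of the repeats has six
pairs. A structure is a pseudoknot iff the partner mapping is
non-monotonic in j along increasing i (checked against a brute-force
oracle); its descriptor is the two dominant registers, sorted decreasing.
Ties between register counts go to the register with the lower-energy
pair block.

The trajectory classifier run-length-encodes per-frame labels (unbound /
register r / two-register monotonic "bulge" / pseudoknot / full duplex),
drops dwells shorter than `dwell_min` (default 10 frames; flickers), and
maps the dwelled sequence to a mechanism: single register throughout →
`zippering`; a dwelled bulge with the new register replacing the old →
`inchworm`; a dwelled non-monotonic intermediate → pseudoknot
displacement; ending unbound → `detachment`. Trajectories showing several
displacement mechanisms are `mixed`, with the ordered mechanism list
recorded and the first displacement mechanism as the headline — the
convention used for, e.g., a register −10 → 2 pseudoknot step followed by
a 2 → 0 inchworm step.

# Synthetic configurations and toys

`build_configuration()` generates every input state: separated
pre-oriented strands (placed at half the box edge, feasibility-checked
against the basin distance), native duplexes and maximal
misaligned-register structures on an idealized helix (rise 0.39, twist
34°, hydrogen-bond-site radius 0.20 — chosen so the built duplex sits at
the hydrogen-bond minimum), and two-block pseudoknots laid on a coaxial
helical track threaded by strand 2, with the second arm folded about the
inter-arm junction by a hinge angle chosen from a grid to minimize
backbone strain. Built pseudoknots are topologically right but
geometrically strained; a few hundred Monte Carlo relaxation sweeps
settle them (the fixtures tests verify that detection reproduces the
requested descriptor both before and, for pair retention, after
relaxation). The generator emulates structured starting states, not
equilibrium ensembles: passing tests show the machinery is correct on
constructed states, and say nothing about, e.g., real single-stranded
stacking ensembles, hairpin-forming sequences (excluded here, as in the
study design) or salt dependence (fixed by parameterization).

The toy systems carry their own oracles: a double-well walker
(V = h(x²−1)² + tilt·x; occupancies by quadrature, rates by brute-force
transition counting) and a two-state dimer (radial coordinate with the 3D
r² measure and a short-range attraction; K_eq by configurational
integral). They validate the Monte Carlo, umbrella and FFS machinery
independently of the DNA model.

# Study conditions and problem sizes

The packaged studies run at desk scale, chosen once: 14-mer campaigns at
300 K and 340.9 K in a box of edge 12 (≈ 1.5 mM strand pairs) with
Langevin dt = 0.005 and diffusion scale 3, 30/80/30 shots across the
three interface stages (the cheap middle stage gets the most shots so the
two-base-pair ensemble is well populated) and per-stage step budgets that
give the final zippering stage the most time;
8-mer sequence-dependence campaigns in a box of edge 10 with the Brownian
thermostat (dt = 2e-4, D_t = 2) and 50/150/100 shots across the three
stages; umbrella production of 24000–40000 sweeps after 8–10 × 2000–2500
adaptation sweeps; toy oracles at 1e7–2e7 brute-force steps and 300–400
shots. At these sizes the stage probabilities carry relative errors of
tens of percent, so the package reports every estimate with its
uncertainty and the acceptance script recomputes ratios and
probabilities, not absolute rates.

Two study conditions deliberately differ from the obvious choices. The
duplex-formation target is n ≥ N−2 base pairs: near the study
temperatures duplex ends breathe, and demanding all N pairs at one
instant would confound the association rate with terminal fraying. And
the sequence-dependence comparison runs at 270 K with the staged order
parameter counting *native* pairs (misaligned bonds fully present in the
model): the A/T- and G/C-only 8-mers are effectively repetitive, so a
total-pair-count target is confounded by long-lived misaligned
intermediates, and at 298 K the A-T-rich duplex sits essentially at this
model's stability edge, making its association rate unobservable at desk
scale. At 270 K both duplexes bind robustly and the relative rate is well
posed. The shipped hydrogen-bond contrast (1.26 vs 0.88) is larger in kT
terms than the effective contrast of nearest-neighbour thermodynamics,
so the computed G-C/A-T rate ratio is much larger than experimental
toehold-binding contrasts; the direction and the reduction of the ratio
when misaligned bonds are forbidden are the meaningful outputs.

# Known limitations

* The parameterization is qualitative: Watson–Crick specificity, G-C >
  A-T, stacking ~ linear in kT, stable B-like duplexes — but not fitted
  to melting thermodynamics; absolute melting temperatures and absolute
  rates are not predictions.
* A single temperature-scale constant cannot match free-energy slopes at
  two temperatures simultaneously; the calibration anchors 300 K.
* Brownian dynamics uses a capped Euler–Maruyama update; the cap is a
  stability device, and equilibrium accuracy of the walkers' overdamped
  dynamics is O(dt) (the Metropolis samplers, not the walkers, are the
  equilibrium references).
* Desk-scale FFS leaves a fraction of final-stage shots unresolved inside
  their step budgets (trapped misaligned intermediates); probabilities are
  conditional on resolution and carry a warning when the fraction exceeds
  10%.
* Intra-strand hairpins, explicit ions/salt dependence, and temperature-
  dependent solvent viscosity are out of scope.
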