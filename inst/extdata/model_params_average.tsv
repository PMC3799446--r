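# Rigid-nucleotide coarse-grained DNA model: sequence-averaged parameterization.
# All values in simulation units (length unit = 0.8518 nm, energy unit =
# kB * 1622 K = 3.2232 kcal/mol; thermal energy kT = T[K] / 1622).
# Keys are validated against a fixed schema by load_parameters().
key	value
schema_version	1
variant	average
# interaction-site offsets along the base-face axis a1 (body frame)
pos_back	-0.40
pos_stack	0.34
pos_hb	0.40
# backbone connectivity (FENE)
fene_eps	4.0
fene_r0	0.70
fene_delta	0.25
# excluded volume (WCA), sigma per site-pair class
exc_eps	2.0
sig_bb	0.55
sig_bs	0.40
sig_ss	0.30
sig_bonded	0.27
# hydrogen bonding (Watson-Crick pairs only)
hb_r0	0.40
hb_wr	0.30
hb_w1	0.80
hb_w2	0.80
hb_eps_at	1.07
hb_eps_gc	1.07
# nearest-neighbour stacking; strength = (st_eta + st_alpha*kT) * g(b5)*g(b3)
st_r0	0.42
st_wr	0.35
st_w1	0.95
st_cref2	0.85
st_w2	0.60
st_eta	1.34
st_alpha	2.66
st_g_a	1.0
st_g_c	1.0
st_g_g	1.0
st_g_t	1.0
# interstrand cross-stacking
cx_eps	0.20
cx_r0	0.63
cx_wr	0.25
cx_w1	0.90
# coaxial stacking (model-family term; disabled in this model version)
coax_on	0
coax_eps	0.30
coax_r0	0.42
coax_wr	0.30
coax_w1	0.80
# unit conversions
sim_length_nm	0.8518
sim_energy_kcal_mol	3.2232
sim_temp_K	1622
# pairing / stacking detection thresholds as fractions of typical term depth
hb_pair_frac	0.15
st_pair_frac	0.15
# idealized duplex geometry used by the configuration builder
helix_rise	0.39
helix_twist_deg	34.0
helix_r_hb	0.20
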