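# Pathway classification, ensemble comparison, Arrhenius analysis and
# rate arithmetic.

test_that("canonical trajectories classify as zippering, inchworm and pseudoknot displacement", {
  expect_identical(classify_transition(zippering_record())$mechanism,
                   "zippering")
  cl_in <- classify_transition(inchworm_record())
  expect_identical(cl_in$mechanism, "inchworm")
  expect_identical(cl_in$end, "full_duplex")
  cl_pk <- classify_transition(pseudoknot_record())
  expect_identical(cl_pk$mechanism, "pseudoknot_displacement")
  expect_identical(cl_pk$start, "register:10")
  expect_identical(classify_transition(detachment_record())$mechanism,
                   "detachment")
})

test_that("flickers below the dwell threshold are ignored", {
  rec <- zippering_record(dwell = 12)
  # splice a 3-frame pseudoknot flicker into the zippering record
  flick <- mk_struct(rbind(pairs_in_register(-6, 0:3),
                           pairs_in_register(6, 8:11)))
  # the flicker is non-monotonic
  expect_false(is.null(flick$pseudoknot))
  frames <- c(rec$structures[1:40], rep_frames(flick, 3),
              rec$structures[41:length(rec$structures)])
  expect_identical(classify_transition(frames, dwell_min = 10)$mechanism,
                   "zippering")
  # but a dwelled pseudoknot changes the call
  frames2 <- c(rec$structures[1:40], rep_frames(flick, 15),
               rec$structures[41:length(rec$structures)])
  expect_identical(classify_transition(frames2, dwell_min = 10)$mechanism,
                   "pseudoknot_displacement")
})

test_that("classification is deterministic and stable under coarser subsampling", {
  rec <- inchworm_record(dwell = 30)
  c1 <- classify_transition(rec, dwell_min = 10)
  c2 <- classify_transition(rec, dwell_min = 10)
  expect_identical(c1, c2)
  sub <- transition_record(rec$structures[seq(1, length(rec$structures), 3)])
  expect_identical(classify_transition(sub, dwell_min = 4)$mechanism,
                   c1$mechanism)
})

test_that("trajectories with both displacement mechanisms are labelled mixed in order", {
  s_r10 <- mk_struct(pairs_in_register(10, 10:13))
  s_pk <- mk_struct(rbind(pairs_in_register(10, 10:13),
                          pairs_in_register(2, 6:9)))
  s_r2 <- mk_struct(pairs_in_register(2, 2:11))
  s_bulge <- mk_struct(rbind(pairs_in_register(2, 6:11),
                             pairs_in_register(0, 0:3)))
  s_done <- mk_struct(pairs_in_register(0, 0:13))
  rec <- transition_record(c(rep_frames(s_r10, 12), rep_frames(s_pk, 12),
                             rep_frames(s_r2, 12), rep_frames(s_bulge, 12),
                             rep_frames(s_done, 12)))
  cl <- classify_transition(rec)
  expect_identical(cl$mechanism, "mixed")
  expect_identical(cl$mechanisms, c("pseudoknot_displacement", "inchworm"))
  expect_error(classify_transition(transition_record(rep_frames(s_r10, 30))),
               "open record")
})

test_that("mechanism census aggregates starts, ends and mechanisms", {
  recs <- list(zippering_record(), zippering_record(), inchworm_record(),
               detachment_record())
  cen <- mechanism_census(recs)
  expect_identical(sum(cen$count), 4)
  expect_identical(cen$count[cen$mechanism == "zippering"], 2)
})

test_that("identical ensembles give zero mean differences", {
  set.seed(51)
  cfg <- build_configuration("gc8", "native_duplex", box = 12,
                             temperature = 300, params = avg_params, seed = 4)
  # condition states on n = 8 by construction
  states <- lapply(1:6, function(k) {
    r <- evolve(cfg, avg_params,
                thermostat_settings("langevin", dt = 0.005),
                n_steps = 2000, seed = 100 + k)
    r$config
  })
  keep <- vapply(states, function(s)
    detect_base_pairs(s, avg_params)$n_total == 8, TRUE)
  states <- states[keep]
  expect_gt(length(states), 2)
  cmp <- ensemble_compare(states, states, n = 8, params = avg_params,
                          n_boot = 200)
  expect_equal(cmp$separation_nm[1], cmp$separation_nm[2])
  expect_equal(cmp$stacking[1], cmp$stacking[2])
  expect_error(ensemble_compare(states, states, n = 3, params = avg_params),
               "conditioning error")
})

test_that("Arrhenius analysis recovers a planted constant activation enthalpy exactly", {
  R <- 0.0019872041
  Tt <- c(300, 310, 320, 330, 340.9)
  dH <- -5
  k <- 1e3 * exp(-dH / (R * Tt))
  fit <- arrhenius_apparent_enthalpy(Tt, k)
  expect_equal(fit$dH_kcal, rep(dH, 4), tolerance = 1e-10)
  # temperature-dependent enthalpy: pairwise slopes track the midpoints
  dH_T <- function(Tk) -2 - 0.03 * (Tk - 300)
  # d ln k / d(1/T) = -dH(T)/R, integrated exactly over each interval
  lnk <- cumsum(c(0, vapply(seq_len(length(Tt) - 1), function(q)
    -integrate(function(u) dH_T(1 / u), 1 / Tt[q], 1 / Tt[q + 1])$value / R,
    0)))
  fit2 <- arrhenius_apparent_enthalpy(Tt, exp(lnk))
  mid <- dH_T(fit2$T_mid)
  expect_lt(max(abs(fit2$dH_kcal - mid)), 0.05)
  expect_error(arrhenius_apparent_enthalpy(c(300, 310), c(1, -1)), "positive")
  expect_error(arrhenius_apparent_enthalpy(c(300, 300), c(1, 2)), "distinct")
  expect_error(arrhenius_apparent_enthalpy(300, 1), "two temperatures")
})

test_that("dissociation rate follows from the equilibrium identity", {
  expect_equal(dissociation_rate_from_equilibrium(1, 1)$k_off, 1)
  expect_equal(dissociation_rate_from_equilibrium(2, 4)$k_off, 0.5)
  expect_error(dissociation_rate_from_equilibrium(-1, 1), "positive")
  expect_error(dissociation_rate_from_equilibrium(1, 0), "positive")
  # toy: k_off from k_on/K matches the directly simulated unbinding rate
  set.seed(52)
  dimer <- make_toy("two_state_dimer")
  K <- toy_Keq_quadrature(dimer)
  kon <- toy_brute_rate(dimer, nsteps = 1.5e7, x0 = 1.5,
                        target = dimer$wpar$rc * 0.6,
                        rearm = dimer$wpar$rc * 1.6)
  koff <- toy_brute_rate(dimer, nsteps = 1.5e7, x0 = dimer$wpar$rc / 2,
                         target = dimer$wpar$rc * 1.6,
                         rearm = dimer$wpar$rc * 0.6)
  pred <- dissociation_rate_from_equilibrium(kon$k, K, kon$se, 0)
  expect_lt(abs(pred$k_off - koff$k), 2 * sqrt(pred$se^2 + koff$se^2))
})

test_that("first-contact statistics report positions along the strand", {
  cfg <- build_configuration("nonrepetitive14", "native_duplex", box = 20,
                             temperature = 300, params = avg_params, seed = 1)
  fc <- first_contact_positions(list(cfg), avg_params)
  expect_identical(nrow(fc), 1L)
  expect_true(fc$rel_position >= 0 && fc$rel_position <= 1)
})
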