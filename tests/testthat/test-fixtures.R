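# Synthetic configuration and toy-system generators.

test_that("sequence presets return the study strand pairs", {
  p <- sequence_presets()
  expect_setequal(names(p), c("nonrepetitive14", "repeat14", "gc8", "avg8",
                              "at8"))
  expect_identical(as.character(sequence_presets("nonrepetitive14")),
                   c("TATCTGGCTTGTCG", "CGACAAGCCAGATA"))
  expect_identical(as.character(sequence_presets("repeat14")),
                   c("ACACACACACACAC", "GTGTGTGTGTGTGT"))
  expect_identical(sequence_presets("gc8")[[1]], "CCCGCCGC")
  expect_identical(sequence_presets("avg8")[[1]], "TCTCCATG")
  expect_identical(sequence_presets("at8")[[1]], "ATTTATTA")
  # every preset's second strand is the reverse complement of the first
  for (pp in p) expect_identical(pp[[2]], reverse_complement(pp[[1]]))
  for (pp in p) expect_true(nzchar(attr(pp, "provenance")))
  expect_error(sequence_presets("nope"), "unknown sequence preset")
})

test_that("every structure mode round-trips through detection", {
  # native duplex: all native pairs formed
  nd <- build_configuration("nonrepetitive14", "native_duplex", box = 20,
                            temperature = 300, params = avg_params, seed = 1)
  expect_identical(detect_base_pairs(nd, avg_params)$n_native, 14L)
  # misaligned(-8) on the repeats: exactly the maximal register pair set
  mi <- build_configuration("repeat14", "misaligned", register = -8,
                            box = 20, temperature = 300,
                            params = avg_params, seed = 2)
  ssm <- detect_base_pairs(mi, avg_params)
  expect_identical(ssm$n_total,
                   max_pairs_in_register("ACACACACACACAC",
                                         "GTGTGTGTGTGTGT", -8))
  expect_true(all(ssm$pairs$register == -8))
  # pseudoknot(6, -6) at mid-strand split
  pk <- build_configuration("repeat14", "pseudoknot", registers = c(6, -6),
                            box = 20, temperature = 300,
                            params = avg_params, seed = 3)
  expect_identical(detect_base_pairs(pk, avg_params)$pseudoknot, c(6L, -6L))
  # separated strands start in the unbound basin
  sep <- build_configuration("nonrepetitive14", "separated_strands", box = 15,
                             temperature = 300, params = avg_params, seed = 4)
  spec <- order_parameter_spec(14, avg_params)
  expect_identical(eval_order_parameter(sep, spec, avg_params), 0)
  # construction is deterministic given the seed
  sep2 <- build_configuration("nonrepetitive14", "separated_strands", box = 15,
                              temperature = 300, params = avg_params, seed = 4)
  expect_identical(sep$com, sep2$com)
})

test_that("infeasible structure requests are rejected", {
  expect_error(build_configuration("repeat14", "misaligned", register = -7,
                                   box = 20, params = avg_params),
               "infeasible register")
  expect_error(build_configuration("repeat14", "pseudoknot",
                                   registers = c(13, -13), box = 20,
                                   params = avg_params),
               "infeasible pseudoknot")
  expect_error(build_configuration("nonrepetitive14", "separated_strands",
                                   box = 4, params = avg_params),
               "infeasible separated_strands")
})

test_that("box edge and strand-pair concentration are mutually consistent", {
  conc <- 1e-4
  box <- concentration_box(conc, avg_params)
  expect_equal(box_concentration(box, avg_params), conc, tolerance = 1e-12)
  cfg <- build_configuration("gc8", "native_duplex", concentration = conc,
                             temperature = 300, params = avg_params, seed = 1)
  expect_equal(box_concentration(cfg$box, avg_params), conc,
               tolerance = 1e-12)
  # a per-pair rate of k converts to k / c as a bimolecular constant
  expect_equal(bimolecular_rate(2.5, box, avg_params), 2.5 / conc,
               tolerance = 1e-12)
})

test_that("toy systems ship with recomputable reference observables", {
  # symmetric double well: occupancies 1/2 by symmetry and by quadrature
  sym <- make_toy("double_well_walker", list(h = 0.4))
  expect_equal(toy_occupancy_quadrature(sym), 0.5, tolerance = 1e-8)
  # tilted well with dF = 2 kT between the states: occupancy ratio e^2
  # (quadrature oracle; the tilt is chosen to plant the ratio)
  kT <- 0.1
  f_ratio <- function(tilt) {
    t2 <- make_toy("double_well_walker", list(h = 0.4, tilt = tilt))
    p <- toy_occupancy_quadrature(t2)
    log(p / (1 - p))
  }
  tilt2 <- uniroot(function(s) f_ratio(s) - 2, c(0.001, 0.2),
                   tol = 1e-10)$root
  t2 <- make_toy("double_well_walker", list(h = 0.4, tilt = tilt2))
  p <- toy_occupancy_quadrature(t2)
  expect_equal(p / (1 - p), exp(2), tolerance = 1e-6)
  # dimer equilibrium constant from the configurational integral
  dimer <- make_toy("two_state_dimer")
  K <- toy_Keq_quadrature(dimer)
  w <- dimer$wpar
  zb <- integrate(function(r) r^2 * exp(w$eps * (1 - (r / w$rc)^2)^2 / w$kT),
                  w$rmin, w$rc)$value
  zu <- integrate(function(r) r^2, w$rc, w$rmax)$value
  expect_equal(K, zb / zu, tolerance = 1e-6)
  expect_error(make_toy("three_state"), "unknown toy kind")
  expect_error(make_toy("two_state_dimer", list(bogus = 1)),
               "unknown toy parameter")
})
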