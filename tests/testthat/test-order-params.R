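# Secondary-structure logic: base-pair detection, registers, pseudoknots,
# register enumeration, staged order parameter.

test_that("a relaxed native duplex reports all native pairs in register 0", {
  cfg <- build_configuration("nonrepetitive14", "native_duplex", box = 20,
                             temperature = 300, params = avg_params, seed = 1)
  ss <- detect_base_pairs(cfg, avg_params)
  expect_identical(ss$n_total, 14L)
  expect_identical(ss$n_native, 14L)
  expect_true(all(ss$pairs$register == 0))
  expect_null(ss$pseudoknot)
  # detection survives thermal relaxation
  th <- thermostat_settings("langevin", dt = 0.005)
  r <- evolve(cfg, avg_params, th, n_steps = 2e4, seed = 2)
  ss2 <- detect_base_pairs(r$config, avg_params)
  # terminal-pair breathing is physical at this temperature
  expect_gte(ss2$n_native, 13L)
})

test_that("constructed register and pseudoknot fixtures are detected as built", {
  cfg <- build_configuration("repeat14", "misaligned", register = -8,
                             box = 20, temperature = 300,
                             params = avg_params, seed = 5)
  ss <- detect_base_pairs(cfg, avg_params)
  expect_identical(ss$n_total, 6L)
  expect_true(all(ss$pairs$register == -8))
  expect_null(ss$pseudoknot)

  pk <- build_configuration("repeat14", "pseudoknot", registers = c(6, -6),
                            box = 20, temperature = 300,
                            params = avg_params, seed = 6)
  ssp <- detect_base_pairs(pk, avg_params)
  expect_identical(ssp$pseudoknot, c(6L, -6L))
})

test_that("detection threshold contract and determinism hold", {
  cfg <- build_configuration("gc8", "native_duplex", box = 15,
                             temperature = 300, params = avg_params, seed = 2)
  expect_error(detect_base_pairs(cfg, avg_params, threshold = 0.1),
               "negative")
  s1 <- detect_base_pairs(cfg, avg_params)
  s2 <- detect_base_pairs(cfg, avg_params)
  expect_identical(s1$pairs, s2$pairs)
  # each base in at most one pair
  expect_false(anyDuplicated(s1$pairs$i) > 0)
  expect_false(anyDuplicated(s1$pairs$j) > 0)
})

test_that("max_pairs_in_register matches direct enumeration", {
  ac <- "ACACACACACACAC"; gt <- "GTGTGTGTGTGTGT"
  # AC/GT repeats: 14 - |r| for even r, 0 for odd r
  for (r in -13:13) {
    expected <- if (r %% 2 == 0) 14 - abs(r) else 0
    expect_identical(max_pairs_in_register(ac, gt, r), as.integer(expected))
  }
  expect_identical(max_pairs_in_register(ac, gt, 0), 14L)
  expect_identical(max_pairs_in_register("TATCTGGCTTGTCG", "CGACAAGCCAGATA", 0), 14L)
  # independent brute-force oracle on random sequences
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    s1 <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    r <- sample(-(n - 1):(n - 1), 1)
    brute <- 0L
    for (i in 0:(n - 1)) {
      j <- n - 1 - i + r
      if (j >= 0 && j < n &&
          is_watson_crick(substr(s1, i + 1, i + 1), substr(s2, j + 1, j + 1)))
        brute <- brute + 1L
    }
    got <- max_pairs_in_register(s1, s2, r)
    expect_identical(got, brute)
    expect_lte(got, n - abs(r))
  }
})

test_that("pseudoknot flag equals the brute-force monotonicity oracle", {
  set.seed(32)
  for (rep in 1:60) {
    n <- sample(6:14, 1)
    k <- sample(2:(n - 2), 1)
    pairs <- data.frame(i = sort(sample(0:(n - 1), k)),
                        j = sample(0:(n - 1), k))
    ss <- secondary_structure(pairs, n)
    expect_identical(!is.null(ss$pseudoknot), brute_pseudoknot(pairs))
  }
})

test_that("the staged order parameter orders progress toward the duplex", {
  spec <- order_parameter_spec(14, avg_params, count = "total")
  sep <- build_configuration("nonrepetitive14", "separated_strands", box = 15,
                             temperature = 300, params = avg_params, seed = 7)
  expect_identical(eval_order_parameter(sep, spec, avg_params), 0)
  dup <- build_configuration("nonrepetitive14", "native_duplex", box = 15,
                             temperature = 300, params = avg_params, seed = 8)
  expect_identical(eval_order_parameter(dup, spec, avg_params), 15)
  # a two-base-pair state scores the penultimate staged value 1 + 2
  two <- dup
  two$com[15:26, ] <- two$com[15:26, ] + 8   # displace strand 2 except 2 nt
  expect_identical(eval_order_parameter(two, spec, avg_params), 3)
  expect_error(eval_order_parameter(dup, list(bogus = 1), avg_params),
               "unknown order-parameter spec")
})

test_that("structure logs serialize counts, registers and pseudoknots", {
  cfg <- build_configuration("repeat14", "misaligned", register = -8,
                             box = 20, temperature = 300,
                             params = avg_params, seed = 5)
  sl <- structure_log(list(detect_base_pairs(cfg, avg_params),
                           secondary_structure(NULL, 14)))
  expect_identical(nrow(sl), 2L)
  expect_identical(sl$n_total, c(6L, 0L))
  expect_match(sl$registers[1], "-8:6")
})
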