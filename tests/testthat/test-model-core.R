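# Potential-energy model: parameter tables, Watson-Crick specificity,
# pair energies, analytic gradients.

test_that("parameter variants encode the intended base dependence", {
  # average variant: identical hydrogen-bond strength for A-T and G-C
  expect_equal(avg_params$cpp$hb_eps_mat["A", "T"],
               avg_params$cpp$hb_eps_mat["G", "C"])
  # sequence-dependent variant: G-C pairs stronger than A-T
  expect_gt(seq_params$cpp$hb_eps_mat["G", "C"],
            seq_params$cpp$hb_eps_mat["A", "T"])
  # hydrogen bonding is nonzero ONLY for Watson-Crick identities
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T")) {
    expected <- is_watson_crick(a, b)
    expect_identical(avg_params$cpp$hb_eps_mat[a, b] > 0, expected)
    expect_identical(seq_params$cpp$hb_eps_mat[a, b] > 0, expected)
  }
  # backbone and excluded-volume constants identical across variants
  for (key in c("fene_eps", "fene_r0", "fene_delta", "exc_eps",
                "sig_bb", "sig_bs", "sig_ss", "sig_bonded"))
    expect_equal(avg_params$values[[key]], seq_params$values[[key]])
})

test_that("parameter loading validates its schema", {
  expect_error(load_parameters("average_typo"), "unknown parameterization")
  # deleting one constant gives a schema error naming the field
  src <- readLines(system.file("extdata", "model_params_average.tsv",
                               package = "hybridkin"))
  broken <- src[!grepl("^st_eta\t", src)]
  tf <- tempfile(fileext = ".tsv")
  writeLines(broken, tf)
  expect_error(load_parameters("average", file = tf), "st_eta")
  # out-of-range constant also names the field
  bad <- sub("^hb_wr\t.*$", "hb_wr\t-0.3", src)
  writeLines(bad, tf)
  expect_error(load_parameters("average", file = tf), "hb_wr")
  # loading is idempotent
  expect_identical(load_parameters("average")$values,
                   load_parameters("average")$values)
})

test_that("Watson-Crick test is correct and symmetric", {
  expect_true(is_watson_crick("A", "T"))
  expect_true(is_watson_crick("C", "G"))
  expect_false(is_watson_crick("A", "G"))
  expect_false(is_watson_crick("A", "C"))
  expect_false(is_watson_crick("A", "A"))
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T"))
    expect_identical(is_watson_crick(a, b), is_watson_crick(b, a))
  expect_error(is_watson_crick("A", "X"), "invalid base")
  # complement is an involution
  for (b in c("A", "C", "G", "T"))
    expect_identical(complement_base(complement_base(b)), b)
})

test_that("pair energies honour cutoffs, symmetry and specificity", {
  set.seed(11)
  cfg <- build_configuration(c("ACGT", "ACGT"), "native_duplex", box = 40,
                             temperature = 300, params = avg_params, seed = 2)
  # far-separated non-bonded nucleotides: every term zero
  far <- cfg
  far$com[5:8, 1] <- far$com[5:8, 1] + 15
  pe <- pair_energy(far, avg_params, 0, 7)
  expect_true(all(pe$terms == 0))
  # overlapping backbone sites deep in the core: repulsive
  ov <- cfg
  ov$com[5, ] <- ov$com[1, ] + c(0.05, 0, 0)
  ov$a1[5, ] <- ov$a1[1, ]; ov$a3[5, ] <- ov$a3[1, ]
  pe2 <- pair_energy(ov, avg_params, 0, 4)
  expect_gt(pe2$terms[["excluded_volume"]], 0)
  # A opposite G in pairing geometry: no hydrogen bonding
  ag <- build_configuration(c("AA", "TT"), "native_duplex", box = 40,
                            temperature = 300, params = avg_params, seed = 3)
  expect_lt(pair_energy(ag, avg_params, 0, 3)$terms[["hydrogen_bonding"]], 0)
  ag$seqs <- c("AA", "TG"); ag$base <- unname(hybridkin:::.base_codes[
    unlist(strsplit(ag$seqs, ""))])
  expect_identical(pair_energy(ag, avg_params, 0, 3)$terms[["hydrogen_bonding"]], 0)
  # symmetry under (i, j) swap, random poses
  set.seed(12)
  for (rep in 1:10) {
    p <- perturb_config(cfg, sd_pos = 0.3, sd_rot = 0.5)
    i <- sample(0:7, 1); j <- sample(setdiff(0:7, i), 1)
    expect_equal(pair_energy(p, avg_params, i, j)$terms,
                 pair_energy(p, avg_params, j, i)$terms)
  }
  expect_error(pair_energy(cfg, avg_params, 0, 0), "i != j")
  expect_error(pair_energy(cfg, avg_params, 0, 99), "out of range")
})

test_that("backbone term appears only between bonded neighbours", {
  cfg <- build_configuration(c("ACGT", "ACGT"), "native_duplex", box = 20,
                             temperature = 300, params = avg_params, seed = 2)
  expect_true(pair_energy(cfg, avg_params, 0, 1)$terms[["backbone"]] != 0)
  expect_identical(pair_energy(cfg, avg_params, 0, 2)$terms[["backbone"]], 0)
  expect_identical(pair_energy(cfg, avg_params, 0, 7)$terms[["backbone"]], 0)
})

test_that("energy is invariant under global translation and rotation", {
  set.seed(13)
  cfg <- perturb_config(
    build_configuration("gc8", "native_duplex", box = 30,
                        temperature = 300, params = avg_params, seed = 5))
  e0 <- total_energy(cfg, avg_params)$energy$total
  tr <- cfg; tr$com <- tr$com + matrix(rep(c(3.1, -2.7, 0.9), each = 16), 16, 3)
  expect_equal(total_energy(tr, avg_params)$energy$total, e0, tolerance = 1e-9)
  rot <- rotate_config_global(cfg, c(1, 2, 3), 0.77)
  expect_equal(total_energy(rot, avg_params)$energy$total, e0, tolerance = 1e-9)
})

test_that("forces and torques equal the negative numerical gradient", {
  set.seed(14)
  for (variant in list(avg_params, seq_params)) {
    cfg <- perturb_config(
      build_configuration(c("ACGT", "ACGT"), "native_duplex", box = 20,
                          temperature = 300, params = variant, seed = 2),
      sd_pos = 0.08, sd_rot = 0.15)
    ft <- forces_torques(cfg, variant)
    num <- numerical_gradients(cfg, variant)
    scale <- max(abs(ft$force), abs(ft$torque))
    expect_lt(max(abs(ft$force - num$force)) / scale, 1e-6)
    expect_lt(max(abs(ft$torque - num$torque)) / scale, 1e-6)
    # Newton's third law and zero net torque for the isolated system
    expect_lt(max(abs(colSums(ft$force))), 1e-10)
    net_tau <- colSums(ft$torque) +
      colSums(t(vapply(seq_len(nrow(cfg$com)), function(i)
        c(cfg$com[i, 2] * ft$force[i, 3] - cfg$com[i, 3] * ft$force[i, 2],
          cfg$com[i, 3] * ft$force[i, 1] - cfg$com[i, 1] * ft$force[i, 3],
          cfg$com[i, 1] * ft$force[i, 2] - cfg$com[i, 2] * ft$force[i, 1]),
        numeric(3))))
    expect_lt(max(abs(net_tau)), 1e-10)
  }
})

test_that("sequence-dependent and average variants agree on backbone and excluded volume", {
  set.seed(15)
  cfg <- perturb_config(
    build_configuration("at8", "native_duplex", box = 20,
                        temperature = 300, params = avg_params, seed = 6),
    sd_pos = 0.2, sd_rot = 0.4)
  ea <- total_energy(cfg, avg_params)$energy$terms
  es <- total_energy(cfg, seq_params)$energy$terms
  expect_equal(ea[["backbone"]], es[["backbone"]])
  expect_equal(ea[["excluded_volume"]], es[["excluded_volume"]])
  # while hydrogen bonding differs (A-T weaker in the sequence-dependent set)
  expect_gt(es[["hydrogen_bonding"]], ea[["hydrogen_bonding"]])
})

test_that("a non-orthonormal frame is rejected", {
  cfg <- build_configuration("gc8", "native_duplex", box = 20,
                             temperature = 300, params = avg_params, seed = 5)
  cfg$a1[3, ] <- cfg$a1[3, ] * 1.2
  expect_error(total_energy(cfg, avg_params), "orthonormal")
})

test_that("native-only switch zeroes non-native hydrogen bonds only", {
  cfg <- build_configuration("repeat14", "misaligned", register = -2,
                             box = 25, temperature = 300,
                             params = avg_params, seed = 8)
  ss_all <- detect_base_pairs(cfg, avg_params)
  expect_gt(ss_all$n_total, 0)
  expect_identical(ss_all$n_native, 0L)
  parN <- set_native_only(avg_params)
  ss_nat <- detect_base_pairs(cfg, parN)
  expect_identical(ss_nat$n_total, 0L)
})
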