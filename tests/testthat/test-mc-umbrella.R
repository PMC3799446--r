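# Cluster-move Monte Carlo and umbrella sampling: Boltzmann sampling
# against quadrature, detailed-balance audit, duplex mobility, exact
# reweighting.

test_that("Metropolis sampling reproduces quadrature occupancies on a toy", {
  set.seed(21)
  toy <- make_toy("double_well_walker", list(h = 0.3, tilt = 0.05))
  oq <- toy_occupancy_quadrature(toy)
  mc <- toy_mc_umbrella(toy, nsteps = 3e5, weights = c(1, 1), sd_prop = 0.3,
                        blocks = 10)
  expect_lt(abs(mc$occupancy - oq), 2 * mc$se + 1e-12)
})

test_that("logged cluster-MC moves obey the Metropolis acceptance rule", {
  set.seed(22)
  cfg <- build_configuration("gc8", "native_duplex", box = 12,
                             temperature = 450, params = avg_params, seed = 4)
  c1 <- vmmc_sweep(cfg, avg_params, n_sweeps = 400, log_moves = TRUE)
  log <- attr(c1, "move_log")
  kT <- sim_kT(450, avg_params)
  p_acc <- mc_accept_prob(log$dE, kT, log$wr)
  # moves with acceptance probability 1 must all be accepted
  expect_true(all(log$accepted[p_acc >= 1 - 1e-12] == 1))
  # for stochastic acceptances, the empirical rate matches the rule (2 sigma)
  sto <- p_acc < 1 - 1e-12 & p_acc > 1e-6
  expect_gt(sum(sto), 100)
  expected <- sum(p_acc[sto])
  observed <- sum(log$accepted[sto])
  se <- sqrt(sum(p_acc[sto] * (1 - p_acc[sto])))
  expect_lt(abs(observed - expected), 2 * se + 1e-9)
})

test_that("bound duplexes diffuse under cluster moves while pairs persist", {
  set.seed(23)
  cfg <- build_configuration("gc8", "native_duplex", box = 12,
                             temperature = 200, params = avg_params, seed = 4)
  c1 <- vmmc_sweep(cfg, avg_params, n_sweeps = 1500, store_stride = 50)
  mc <- attr(c1, "mc")
  expect_identical(detect_base_pairs(c1, avg_params)$n_native, 8L)
  coms <- t(vapply(mc$frames, function(f) colMeans(f$com), numeric(3)))
  half <- nrow(coms) %/% 2
  msd_half <- sum((coms[half, ] - coms[1, ])^2)
  msd_full <- sum((coms[nrow(coms), ] - coms[1, ])^2)
  expect_gt(msd_half, 0.5)
  expect_gt(msd_full, msd_half * 0.5)  # keeps growing, not bounded rattling
})

test_that("uniform umbrella weights recover the plain estimate", {
  set.seed(24)
  toy <- make_toy("two_state_dimer")
  plain <- toy_mc_umbrella(toy, nsteps = 6e5, weights = c(1, 1), blocks = 8)
  quad <- toy_occupancy_quadrature(toy)
  expect_lt(abs(plain$occupancy - quad), 2 * plain$se + 1e-12)
  # reweighting with uniform weights is the identity
  counts <- c(37, 101, 12)
  expect_equal(reweight_histogram(counts, 1), counts / sum(counts))
})

test_that("strong umbrella bias recovers the exact free-energy difference", {
  set.seed(25)
  toy <- make_toy("two_state_dimer")
  dF_exact <- toy_deltaF_quadrature(toy)
  u <- toy_mc_umbrella(toy, nsteps = 4e5, weights = c(60, 1))
  dF_est <- -log((1 - u$occupancy) / u$occupancy)
  se_dF <- u$se / (u$occupancy * (1 - u$occupancy))
  expect_lt(abs(dF_est - dF_exact), 2 * se_dF)
  # the bias did its job: the rare bound state is now well sampled
  expect_gt(min(u$counts), 0.2 * sum(u$counts))
})

test_that("umbrella profiles mark unvisited n as unsampled", {
  set.seed(26)
  cfg <- build_configuration("gc8", "native_duplex", box = 12,
                             temperature = 300, params = avg_params, seed = 4)
  parN <- set_native_only(avg_params)
  w <- rep(1, 9); w[1] <- 1e-9
  prof <- run_umbrella(cfg, parN, bias_spec(w, "n_native"), sweeps = 800,
                       n_blocks = 4, seed = 27)
  expect_true(any(!prof$sampled))
  expect_true(all(is.na(prof$F_kT[!prof$sampled])))
  expect_equal(min(prof$F_kT, na.rm = TRUE), 0)
  expect_equal(sum(prof$P, na.rm = TRUE), 1)
  expect_error(bias_spec(c(1, -1, 1)), "positive")
})

test_that("umbrella sampling of the short duplex spans the base-pair range", {
  set.seed(28)
  cfg <- build_configuration(c("GCAGC", "GCTGC"), "native_duplex", box = 12,
                             temperature = 360, params = avg_params, seed = 4)
  parN <- set_native_only(avg_params)
  bias <- adapt_umbrella_weights(cfg, parN, n_max = 5, n_iter = 12,
                                 sweeps_per_iter = 1500)
  prof <- run_umbrella(cfg, parN, bias, sweeps = 10000, n_blocks = 5, seed = 29)
  expect_true(all(prof$sampled[prof$n >= 2 & prof$n <= 5]))
  # bound-state free energy decreases toward the full duplex at this T
  f <- prof$F_kT[prof$sampled & prof$n >= 2]
  expect_lt(f[length(f)], f[1])
})
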