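# Langevin/Brownian propagation: determinism, drag limit, energy
# conservation, thermostat validation against closed-form oracles.

test_that("propagation is reproducible for a fixed seed", {
  cfg <- build_configuration(c("AC", "GT"), "native_duplex", box = 15,
                             temperature = 300, params = avg_params, seed = 3)
  th <- thermostat_settings("langevin", dt = 0.005)
  r1 <- evolve(cfg, avg_params, th, n_steps = 500, seed = 42)
  r2 <- evolve(cfg, avg_params, th, n_steps = 500, seed = 42)
  expect_identical(r1$config$com, r2$config$com)
  expect_identical(r1$config$vel, r2$config$vel)
  r3 <- evolve(cfg, avg_params, th, n_steps = 500, seed = 43)
  expect_false(identical(r1$config$com, r3$config$com))
})

test_that("pure drag at zero temperature decays velocity monotonically", {
  cfg <- configuration("A", com = matrix(0, 1, 3),
                       a1 = matrix(c(1, 0, 0), 1, 3),
                       a3 = matrix(c(0, 0, 1), 1, 3),
                       vel = matrix(c(2, 0, 0), 1, 3),
                       box = 100, temperature = 0)
  th <- thermostat_settings("langevin", dt = 0.01, gamma_t = 0.5, gamma_r = 0.5)
  r <- evolve(cfg, avg_params, th, n_steps = 2000, stride = 100, seed = 1)
  sp <- r$energies$ekin
  expect_true(all(diff(sp) <= 1e-12))
  expect_lt(sp[length(sp)], 1e-6 * sp[1])
})

test_that("zero-friction integration conserves energy", {
  cfg <- build_configuration(c("AC", "GT"), "native_duplex", box = 15,
                             temperature = 300, params = avg_params, seed = 3)
  th <- thermostat_settings("langevin", dt = 0.0015, gamma_t = 0, gamma_r = 0)
  r <- evolve(cfg, avg_params, th, n_steps = 1e4, stride = 100, seed = 11)
  drift <- abs(r$energies$total[nrow(r$energies)] - r$energies$total[1])
  expect_lt(drift, 1e-4)
})

test_that("free-particle diffusion recovers the input coefficient within 5%", {
  set.seed(5)
  n <- 128
  free <- configuration(rep("A", n),
                        com = matrix(runif(n * 3, 0, 500), n, 3),
                        a1 = matrix(rep(c(1, 0, 0), each = n), n, 3),
                        a3 = matrix(rep(c(0, 0, 1), each = n), n, 3),
                        box = 1000, temperature = 300)
  th <- thermostat_settings("langevin", D_t = 1, D_r = 3, dt = 0.01)
  r <- evolve(free, avg_params, th, n_steps = 4e4, stride = 1000,
              store_frames = TRUE, seed = 5)
  # multi-origin MSD fit with intercept: the slope gives the asymptotic
  # diffusion coefficient, the intercept absorbs the inertial offset
  nf <- length(r$frames)
  lags <- 5:20
  msd <- vapply(lags, function(L)
    mean(vapply(seq_len(nf - L), function(k)
      mean(rowSums((r$frames[[k + L]]$com - r$frames[[k]]$com)^2)), 0)), 0)
  lag_t <- lags * 1000 * 0.01
  D_est <- unname(coef(lm(msd ~ lag_t))[2] / 6)
  expect_lt(abs(D_est - 1), 0.05)
})

test_that("interacting system equilibrates to kT/2 per degree of freedom within 3%", {
  cfg <- build_configuration(c("AC", "GT"), "native_duplex", box = 15,
                             temperature = 300, params = avg_params, seed = 3)
  th <- thermostat_settings("langevin", D_t = 0.1, D_r = 0.3, dt = 0.003)
  r <- evolve(cfg, avg_params, th, n_steps = 4e5, stride = 50, seed = 7)
  kT <- sim_kT(300, avg_params)
  per_dof <- mean(r$energies$ekin[-(1:200)]) / (6 * 4)
  expect_lt(abs(per_dof / (kT / 2) - 1), 0.03)
})

test_that("the Brownian scheme samples the same duplex ensemble", {
  cfg <- build_configuration(c("GCAGC", "GCTGC"), "native_duplex", box = 12,
                             temperature = 250, params = avg_params, seed = 4)
  th <- thermostat_settings("brownian", D_t = 0.5, D_r = 1.5, dt = 2e-4)
  r <- evolve(cfg, avg_params, th, n_steps = 5e4, seed = 8)
  ss <- detect_base_pairs(r$config, avg_params)
  # duplex intact (terminal-pair breathing at the snapshot is physical)
  expect_gte(ss$n_native, 4L)
  expect_identical(ss$n_total, ss$n_native)
  expect_error(thermostat_settings("brownian") |>
                 (\(t) evolve({cfg$temperature <- 0; cfg}, avg_params, t, 10))(),
               "temperature > 0")
})

test_that("reduced diffusion leaves equilibrium structure unchanged", {
  cfg <- build_configuration(c("GCAGC", "GCTGC"), "native_duplex", box = 12,
                             temperature = 250, params = avg_params, seed = 4)
  th_slow <- thermostat_settings("langevin", dt = 0.005, diffusion_scale = 0.1)
  r <- evolve(cfg, avg_params, th_slow, n_steps = 2e4, seed = 9)
  expect_identical(detect_base_pairs(r$config, avg_params)$n_native, 5L)
})
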