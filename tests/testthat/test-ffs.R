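# Forward flux sampling: arithmetic contracts, toy-system oracles,
# interface-placement invariance, commitment probabilities.

test_that("interface sets must increase and contain the basin", {
  expect_error(interface_set(c(1, 1, 3)), "strictly increasing")
  expect_error(interface_set(c(1, 2, 3), basin = 1.5), "below the first")
  expect_silent(interface_set(c(1, 2, 3, 15)))
})

test_that("rate composition follows k = Phi0 * prod(p)", {
  mk_run <- function(phi0, nc, p, shots = 100) {
    structure(list(
      flux = list(phi0 = phi0, se = phi0 / sqrt(nc), n_crossings = nc,
                  time = nc / phi0),
      stages = lapply(seq_along(p), function(k)
        list(p = p[k], se = sqrt(p[k] * (1 - p[k]) / shots),
             successes = round(p[k] * shots), n_shots = shots,
             lambda = k)),
      interfaces = interface_set(c(0.5, seq_along(p)), basin = 0.25),
      halted = FALSE, seed = 1,
      conditions = list(kind = "toy")), class = "ffs_run")
  }
  # all p = 1: k = Phi0
  expect_equal(estimate_rate(mk_run(2.5, 100, c(1, 1)))$k, 2.5)
  # p = (0.5, 0.5), Phi0 = 2: k = 0.5
  expect_equal(estimate_rate(mk_run(2, 100, c(0.5, 0.5)))$k, 0.5)
  # incomplete record refuses composition
  bad <- mk_run(2, 100, c(0.5, 0.5))
  bad$stages <- bad$stages[1]
  expect_error(estimate_rate(bad), "missing interface stages")
  halted <- mk_run(2, 100, c(0.5, 0))
  halted$halted <- TRUE
  expect_error(estimate_rate(halted), "incomplete")
})

test_that("a degenerate interface is crossed with probability 1", {
  set.seed(41)
  toy <- make_toy("double_well_walker", list(h = 0.4))
  sim <- walker_ffs_sim(toy)
  fl <- measure_initial_flux(sim, interface_set(c(-0.6, 0.9), basin = -0.9),
                             min_crossings = 30, max_steps = 1e6)
  st <- shoot_interface(fl$states, sim, -0.6, n_shots = 20)
  expect_identical(st$p, 1)
  expect_identical(st$successes, 20L)
  expect_error(shoot_interface(list(), sim, 0, 10), "empty")
})

test_that("initial flux matches direct crossing counting on the toy", {
  set.seed(42)
  toy <- make_toy("double_well_walker", list(h = 0.4))
  sim <- walker_ffs_sim(toy)
  ifs <- interface_set(c(-0.6, -0.2, 0.2, 0.9), basin = -0.9)
  f1 <- measure_initial_flux(sim, ifs, min_crossings = 300, max_steps = 2e7)
  f2 <- measure_initial_flux(sim, ifs, min_crossings = 300, max_steps = 2e7)
  # two independent measurements of the same flux agree within 2 sigma
  expect_lt(abs(f1$phi0 - f2$phi0), 2 * sqrt(f1$se^2 + f2$se^2))
  # stored states all lie at or beyond the first interface
  expect_true(all(unlist(f1$states) >= -0.6))
})

test_that("composed FFS rate equals the brute-force rate within 2 sigma", {
  set.seed(43)
  toy <- make_toy("double_well_walker", list(h = 0.4))
  br <- toy_brute_rate(toy, nsteps = 2e7)
  sim <- walker_ffs_sim(toy)
  est <- estimate_rate(run_ffs(sim, interface_set(c(-0.6, -0.2, 0.2, 0.9),
                                                  basin = -0.9),
                               n_shots = 400, min_crossings = 200, seed = 7))
  expect_lt(abs(est$k - br$k), 2 * sqrt(est$se^2 + br$se^2))
  # and is invariant to interface placement within 2 sigma
  est2 <- estimate_rate(run_ffs(sim, interface_set(c(-0.7, -0.35, 0, 0.35, 0.9),
                                                   basin = -0.9),
                                n_shots = 400, min_crossings = 200, seed = 8))
  expect_lt(abs(est2$k - est$k), 2 * sqrt(est$se^2 + est2$se^2))
  # every estimate carries its uncertainty
  expect_true(is.finite(est$se) && est$se > 0)
  expect_length(est$ci, 2)
})

test_that("rate ratios at different noise levels match brute force", {
  set.seed(44)
  hot <- make_toy("double_well_walker", list(h = 0.4, kT = 0.12))
  cold <- make_toy("double_well_walker", list(h = 0.4, kT = 0.09))
  ifs <- interface_set(c(-0.6, -0.2, 0.2, 0.9), basin = -0.9)
  e_hot <- estimate_rate(run_ffs(walker_ffs_sim(hot), ifs, n_shots = 300,
                                 min_crossings = 150, seed = 9))
  e_cold <- estimate_rate(run_ffs(walker_ffs_sim(cold), ifs, n_shots = 300,
                                  min_crossings = 150, seed = 10))
  b_hot <- toy_brute_rate(hot, nsteps = 2e7)
  b_cold <- toy_brute_rate(cold, nsteps = 4e7)
  r_ffs <- e_hot$k / e_cold$k
  r_brute <- b_hot$k / b_cold$k
  se_ffs <- r_ffs * sqrt((e_hot$se / e_hot$k)^2 + (e_cold$se / e_cold$k)^2)
  se_brute <- r_brute * sqrt((b_hot$se / b_hot$k)^2 + (b_cold$se / b_cold$k)^2)
  expect_lt(abs(r_ffs - r_brute), 2 * sqrt(se_ffs^2 + se_brute^2))
})

test_that("commitment probability is 1 for states already at the target", {
  toy <- make_toy("double_well_walker", list(h = 0.4))
  sim <- walker_ffs_sim(toy)
  cp <- commit_probability(list(0.95, 0.92), sim, lambda_target = 0.9,
                           n_shots = 10, seed = 1)
  expect_identical(cp$p, 1.0)
  expect_identical(cp$se, 0.0)
})

test_that("relative rates refuse incomparable run conditions", {
  set.seed(45)
  toy <- make_toy("double_well_walker", list(h = 0.4))
  ifs <- interface_set(c(-0.6, -0.2, 0.2, 0.9), basin = -0.9)
  a <- estimate_rate(run_ffs(walker_ffs_sim(toy), ifs, n_shots = 150,
                             min_crossings = 80, seed = 11))
  b <- a
  expect_equal(relative_rate(a, b)$ratio, 1.0)
  b$conditions$dt <- a$conditions$dt * 10
  expect_error(relative_rate(a, b), "comparability")
})
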