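#!/usr/bin/env Rscript
# Thermostat validation: free-particle diffusion against the Einstein
# relation, equipartition on an interacting system, and energy conservation
# of the zero-friction integrator. Writes results/02_thermostats/.

suppressPackageStartupMessages(library(hybridkin))
params <- load_parameters("average")

message("Free-particle diffusion (128 nucleotides, 4e4 steps) ...")
set.seed(10)
n <- 128
free <- configuration(rep("A", n),
                      com = matrix(runif(n * 3, 0, 500), n, 3),
                      a1 = matrix(rep(c(1, 0, 0), each = n), n, 3),
                      a3 = matrix(rep(c(0, 0, 1), each = n), n, 3),
                      box = 1000, temperature = 300)
th <- thermostat_settings("langevin", D_t = 1, D_r = 3, dt = 0.01)
r <- evolve(free, params, th, n_steps = 4e4, stride = 1000,
            store_frames = TRUE, seed = 10)
nf <- length(r$frames)
lags <- 5:20
msd <- vapply(lags, function(L)
  mean(vapply(seq_len(nf - L), function(k)
    mean(rowSums((r$frames[[k + L]]$com - r$frames[[k]]$com)^2)), 0)), 0)
D_est <- unname(coef(lm(msd ~ I(lags * 10)))[2] / 6)
message(sprintf("  D_est = %.4f (input 1.0)", D_est))

message("Equipartition on the 4-nucleotide duplex ...")
cfg <- build_configuration(c("AC", "GT"), "native_duplex", box = 15,
                           temperature = 300, params = params, seed = 3)
th2 <- thermostat_settings("langevin", D_t = 0.1, D_r = 0.3, dt = 0.003)
re <- evolve(cfg, params, th2, n_steps = 4e5, stride = 50, seed = 11)
kT <- sim_kT(300, params)
equip <- mean(re$energies$ekin[-(1:200)]) / 24 / (kT / 2)
message(sprintf("  kinetic energy per dof / (kT/2) = %.4f", equip))

message("Zero-friction energy conservation ...")
th0 <- thermostat_settings("langevin", dt = 0.0015, gamma_t = 0, gamma_r = 0)
rc <- evolve(cfg, params, th0, n_steps = 1e4, stride = 100, seed = 12)
drift <- abs(rc$energies$total[nrow(rc$energies)] - rc$energies$total[1])
message(sprintf("  |energy drift| over 1e4 steps = %.2e", drift))

write_results(list(
  config = list(study = "thermostats", D_t = 1, D_r = 3,
                dt_diffusion = 0.01, dt_equip = 0.003, dt_nve = 0.0015),
  seeds = c(placement = 10, diffusion = 10, equip = 11, nve = 12),
  tables = list(msd = data.frame(lag_time = lags * 10, msd = msd)),
  summary = list(D_estimate = D_est, equipartition_ratio = equip,
                 nve_energy_drift = drift)),
  "results/02_thermostats")
message("Done: results/02_thermostats/")
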