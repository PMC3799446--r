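#!/usr/bin/env Rscript
# Association of the non-repetitive 14-mers: staged FFS at 300 K and
# 340.9 K, commitment probabilities at the two-base-pair (penultimate)
# interface, the native-only comparison, and the apparent activation
# enthalpy from the rate pair. Accelerated diffusion (scale 3) is a logged
# run condition shared by every campaign, so the relative quantities are
# comparable. Writes results/05_hybridization_rates/.

suppressPackageStartupMessages(library(hybridkin))

params <- load_parameters("average")
th <- thermostat_settings("langevin", dt = 0.005, diffusion_scale = 3)
campaign <- function(temperature, params, count, seed) {
  hybridization_ffs("nonrepetitive14", temperature, box = 12,
                    params = params, thermo = th, count = count,
                    n_shots = c(30, 80, 30), min_crossings = 30,
                    max_steps_flux = 6e6, max_steps_shot = c(1e5, 1e5, 5e5),
                    seed = seed)
}

message("FFS campaign at 300 K (misaligned bonds allowed) ...")
run300 <- campaign(300, params, "total", seed = 50)
est300 <- estimate_rate(run300)
message("FFS campaign at 340.9 K ...")
run341 <- campaign(340.9, params, "total", seed = 51)
est341 <- estimate_rate(run341)
message("FFS campaign at 300 K, native-only hydrogen bonding ...")
runN <- campaign(300, set_native_only(params), "native", seed = 52)
estN <- estimate_rate(runN)

# the final-stage probability is the commitment probability of the
# two-base-pair (penultimate-interface) ensemble
commit <- function(run) run$stages[[length(run$stages)]]
arr <- arrhenius_apparent_enthalpy(c(300, 340.9), c(est300$k, est341$k),
                                   c(est300$se, est341$se))
ratioT <- relative_rate(est341, est300)
ratio_native <- relative_rate(estN, est300)

message(sprintf("  k(300) = %.3g, k(340.9) = %.3g, ratio = %.2f",
                est300$k, est341$k, ratioT$ratio))
message(sprintf("  commit from 2 bp: %.0f%% at 300 K, %.0f%% at 340.9 K, %.0f%% native-only",
                100 * commit(run300)$p, 100 * commit(run341)$p,
                100 * commit(runN)$p))
message(sprintf("  apparent activation enthalpy: %.1f +/- %.1f kcal/mol",
                arr$dH_kcal, arr$se_kcal))

# kinetic vs equilibrium ensembles at two base pairs: states reaching the
# penultimate FFS interface vs umbrella-equilibrium states conditioned on
# the same n
message("Kinetic vs equilibrium two-base-pair ensembles ...")
tmpl20 <- build_configuration("nonrepetitive14", "separated_strands",
                              box = 12, temperature = 300, params = params,
                              seed = 50)
as_cfg <- function(st, tmpl) {
  cfg <- tmpl
  cfg$com <- st$com; cfg$a1 <- st$a1; cfg$a3 <- st$a3
  cfg$vel <- st$vel; cfg$ang <- st$ang
  cfg
}
kin_all <- lapply(run300$stage_states[[3]], as_cfg, tmpl = tmpl20)
kin_n <- vapply(kin_all, function(c) detect_base_pairs(c, params)$n_total, 0L)
# states are stored at the first order-parameter check past the interface,
# so some carry more than two pairs; condition both ensembles on the most
# frequent stored pair count
n_star <- as.integer(names(sort(table(kin_n), decreasing = TRUE))[1])
kin2 <- kin_all[kin_n == n_star]
message(sprintf("  conditioning both ensembles on n = %d (%d kinetic states)",
                n_star, length(kin2)))
# the biased equilibrium chain starts from a two-base-pair state (melting a
# full duplex down to n = 2 against its own stability is much slower than
# decorrelating within the n = 2 manifold)
eq_start <- if (length(kin2) > 0) kin2[[1]] else
  build_configuration("nonrepetitive14", "native_duplex", box = 12,
                      temperature = 300, params = params, seed = 53)
set.seed(54)
w2 <- exp(-8 * abs(0:14 - n_star)); w2[1] <- 1e-12  # pin the bias at n_star
eq_run <- vmmc_sweep(eq_start, params, n_sweeps = 20000,
                     bias = bias_spec(w2, "n_total"), store_stride = 40)
mc <- attr(eq_run, "mc")
eq2 <- lapply(which(mc$frame_n == n_star), function(k)
  as_cfg(mc$frames[[k]], tmpl20))
eq2 <- eq2[vapply(eq2, function(c)
  detect_base_pairs(c, params)$n_total == n_star, TRUE)]
cmp <- if (length(kin2) >= 3 && length(eq2) >= 3)
  ensemble_compare(kin2, eq2, n = n_star, params = params) else NULL
if (!is.null(cmp)) {
  message(sprintf("  native-partner separation: kinetic %.2f nm, equilibrium %.2f nm",
                  cmp$separation_nm[1], cmp$separation_nm[2]))
}

# where along the strand do first contacts sit? (contact-interface states)
tmpl <- build_configuration("nonrepetitive14", "separated_strands", box = 12,
                            temperature = 300, params = params, seed = 50)
contact_cfgs <- lapply(run300$stage_states[[1]], function(st) {
  cfg <- tmpl
  cfg$com <- st$com; cfg$a1 <- st$a1; cfg$a3 <- st$a3
  cfg$vel <- st$vel; cfg$ang <- st$ang
  cfg
})
fc <- first_contact_positions(contact_cfgs, params)
message(sprintf("  first contacts: mean position %.2f (0 = 5' end of strand 1)",
                mean(fc$rel_position)))

stage_table <- function(run, label) {
  do.call(rbind, lapply(run$stages, function(s)
    data.frame(campaign = label, lambda = s$lambda, p = s$p, se = s$se,
               successes = s$successes, n_shots = s$n_shots)))
}
write_results(list(
  config = list(study = "hybridization_rates", sequences = "nonrepetitive14",
                box = 12, thermostat = "langevin", dt = 0.005,
                diffusion_scale = 3, n_shots = 40),
  seeds = c(T300 = 50, T341 = 51, native300 = 52),
  tables = list(
    stages = rbind(stage_table(run300, "300K"), stage_table(run341, "341K"),
                   stage_table(runN, "300K_native_only")),
    rates = data.frame(campaign = c("300K", "341K", "300K_native_only"),
                       phi0 = c(run300$flux$phi0, run341$flux$phi0,
                                runN$flux$phi0),
                       k = c(est300$k, est341$k, estN$k),
                       se = c(est300$se, est341$se, estN$se)),
    first_contacts = fc,
    ensemble_comparison = if (!is.null(cmp)) as.data.frame(cmp) else
      data.frame()),
  summary = list(
    k_300K = est300$k, k_341K = est341$k,
    rate_ratio_341_over_300 = ratioT$ratio,
    commit_2bp_300K = commit(run300)$p,
    commit_2bp_341K = commit(run341)$p,
    commit_2bp_native_only_300K = commit(runN)$p,
    apparent_dH_kcal = arr$dH_kcal,
    native_only_over_full_300K = ratio_native$ratio)),
  "results/05_hybridization_rates")
message("Done: results/05_hybridization_rates/")
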