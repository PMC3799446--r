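# Direct forward flux sampling: initial-flux measurement, interface
# shooting, rate composition, and commitment probabilities.
#
# The engine is generic over a "simulator" object providing
#   $flux_chunk(state, lam0, max_steps, target_crossings) and
#   $shoot(state, lam_up, max_steps)
# so the same estimator runs on the DNA model (Langevin/Brownian
# propagation with the staged order parameter) and on the 1D toy systems
# used as brute-force oracles.

#' Ordered FFS interface set
#'
#' @param lambdas strictly increasing interface values; the last is the
#'   full-duplex (target) criterion
#' @param basin lambda value at or below which the system is back in the
#'   unbound basin A
#' @export
interface_set <- function(lambdas, basin = 0.25) {
  if (any(diff(lambdas) <= 0)) stop("interfaces must be strictly increasing")
  if (basin >= lambdas[1]) stop("basin must lie below the first interface")
  structure(list(lambdas = lambdas, basin = basin), class = "interface_set")
}

#' DNA-model FFS simulator
#'
#' @param config0 initial `dna_config` in the unbound basin
#' @param params a `model_parameters` object
#' @param thermo a `thermostat_settings` object
#' @param opspec an `op_spec` staged order parameter
#' @param check_every steps between order-parameter evaluations
#' @return an `ffs_sim` object
#' @export
dna_ffs_sim <- function(config0, params, thermo, opspec, check_every = 10) {
  kT <- sim_kT(config0$temperature, params)
  cth <- .thermo_cpp(thermo, kT)
  base_args <- .cpp_args(config0, params)
  with_state <- function(state) {
    a <- base_args
    a$com <- state$com; a$a1 <- state$a1; a$a3 <- state$a3
    a$vel <- state$vel; a$ang <- state$ang
    a
  }
  structure(list(
    state0 = .get_state(config0),
    dt = thermo$dt,
    lambda = function(state)
      do.call(cpp_lambda, c(with_state(state), list(opspec = unclass(opspec)))),
    flux_chunk = function(state, lam0, lam_target, max_steps, target_crossings)
      do.call(cpp_flux_run, c(with_state(state),
        list(thermo = cth, opspec = unclass(opspec), lam0 = lam0,
             lam_basin = 0, lam_target = lam_target,
             target_crossings = as.integer(target_crossings),
             max_steps = as.integer(max_steps),
             check_every = as.integer(check_every)))),
    shoot = function(state, lam_up, max_steps)
      do.call(cpp_run_until, c(with_state(state),
        list(thermo = cth, opspec = unclass(opspec), lam_up = lam_up,
             lam_down = 0, max_steps = as.integer(max_steps),
             check_every = as.integer(check_every)))),
    conditions = list(kind = "dna", scheme = thermo$scheme,
                      temperature = config0$temperature, box = config0$box,
                      diffusion_scale = thermo$diffusion_scale,
                      D_t = thermo$D_t, D_r = thermo$D_r,
                      dt = thermo$dt, native_only = params$cpp$native_only)
  ), class = "ffs_sim")
}

#' Toy-walker FFS simulator
#' @param toy a `toy_system` from [make_toy()] (kind `double_well_walker`
#'   or `two_state_dimer`)
#' @param basin lambda value re-arming the flux counter
#' @export
walker_ffs_sim <- function(toy, basin = NULL) {
  wpar <- toy$wpar
  if (is.null(basin)) basin <- toy$basin
  structure(list(
    state0 = toy$x0,
    dt = wpar$dt,
    lambda = function(state) state,
    flux_chunk = function(state, lam0, lam_target, max_steps, target_crossings) {
      r <- cpp_walker_flux(state, wpar, lam0, basin, lam_target,
                           as.integer(target_crossings),
                           as.integer(max_steps))
      list(states = as.list(r$states), steps = r$steps,
           steps_in_A = r$steps_in_A, n_crossings = r$n_crossings)
    },
    shoot = function(state, lam_up, max_steps) {
      r <- cpp_walker_until(state, wpar, lam_up, basin, as.integer(max_steps))
      list(state = r$x, hit = r$hit, steps = r$steps)
    },
    conditions = list(kind = toy$kind, dt = wpar$dt, D = wpar$D,
                      kT = wpar$kT, diffusion_scale = 1)
  ), class = "ffs_sim")
}

#' Measure the initial flux through the first interface
#'
#' Counts effective positive crossings of the first interface from basin A
#' per unit simulation time attached to the basin (excursions beyond the
#' target interface are excluded from the time normalization) and stores
#' the crossing states.
#'
#' @param sim an `ffs_sim`
#' @param interfaces an `interface_set`
#' @param min_crossings crossings to collect
#' @param max_steps step budget
#' @return list with `phi0` (flux), `se`, `states`, `steps`, `time`
#' @export
measure_initial_flux <- function(sim, interfaces, min_crossings = 50,
                                 max_steps = 1e7) {
  lams <- interfaces$lambdas
  r <- sim$flux_chunk(sim$state0, lams[1], lams[length(lams)], max_steps,
                      min_crossings)
  if (r$n_crossings == 0)
    stop("initial-flux budget exhausted: no crossing of the first ",
         "interface within ", max_steps, " steps (final lambda unknown; ",
         "consider a smaller box, higher temperature or larger budget)")
  tt <- r$steps_in_A * sim$dt
  phi0 <- r$n_crossings / tt
  list(phi0 = phi0, se = phi0 / sqrt(r$n_crossings), states = r$states,
       n_crossings = r$n_crossings, steps = r$steps, time = tt)
}

#' Shoot from stored interface states toward the next interface
#'
#' Each shot starts from a uniformly drawn stored state with fresh noise;
#' success means reaching `lam_next` before returning to basin A.
#'
#' @param states list of stored states at the current interface
#' @param sim an `ffs_sim`
#' @param lam_next next interface value
#' @param n_shots number of shots
#' @param max_steps per-shot step budget
#' @return list with `p` (success probability), `se` (binomial), `successes`,
#'   `n_shots`, `states` (reached states), `halted` flag
#' @export
shoot_interface <- function(states, sim, lam_next, n_shots, max_steps = 1e6) {
  if (length(states) == 0) stop("empty interface state store")
  succ <- 0L; fail <- 0L; unresolved <- 0L
  reached <- list()
  for (s in seq_len(n_shots)) {
    st <- states[[sample.int(length(states), 1)]]
    r <- sim$shoot(st, lam_next, max_steps)
    if (r$hit == 1) {
      succ <- succ + 1L
      reached[[length(reached) + 1]] <- r$state
    } else if (r$hit == -1) fail <- fail + 1L
    else unresolved <- unresolved + 1L
  }
  resolved <- succ + fail
  if (resolved == 0L)
    stop("no shot resolved within the step budget at interface lambda = ",
         lam_next, "; increase max_steps")
  if (unresolved > 0.1 * n_shots)
    warning(unresolved, " of ", n_shots, " shots at interface lambda = ",
            lam_next, " exhausted the step budget; the probability uses ",
            "resolved shots only")
  p <- succ / resolved
  out <- list(p = p, se = sqrt(p * (1 - p) / resolved), successes = succ,
              n_shots = resolved, n_unresolved = unresolved,
              states = reached, halted = succ == 0L)
  if (succ == 0L)
    warning("all resolved shots failed at interface lambda = ", lam_next,
            "; rate composition halts here")
  out
}

#' Run a complete direct-FFS campaign
#'
#' @param sim an `ffs_sim`
#' @param interfaces an `interface_set`
#' @param n_shots shots per interface (scalar or per-interface vector)
#' @param max_steps_shot per-shot step budget (scalar or per-interface
#'   vector; the final, zippering stage typically needs the largest)
#' @param min_crossings crossings for the initial-flux stage
#' @param max_steps_flux,max_steps_shot step budgets
#' @param seed RNG seed (mandatory for reproducibility)
#' @return an `ffs_run` record with the flux stage, per-interface stages,
#'   stored states at the final reached interface, and run conditions
#' @export
run_ffs <- function(sim, interfaces, n_shots = 100, min_crossings = 50,
                    max_steps_flux = 1e7, max_steps_shot = 1e6, seed = 1,
                    keep_states = FALSE) {
  set.seed(seed)
  lams <- interfaces$lambdas
  flux <- measure_initial_flux(sim, interfaces, min_crossings, max_steps_flux)
  n_stage <- length(lams) - 1
  shots <- rep_len(n_shots, n_stage)
  stages <- vector("list", n_stage)
  stage_states <- if (keep_states) list(flux$states) else NULL
  states <- flux$states
  halted <- FALSE
  for (k in seq_len(n_stage)) {
    st <- shoot_interface(states, sim, lams[k + 1], shots[k],
                          rep_len(max_steps_shot, n_stage)[k])
    stages[[k]] <- st[c("p", "se", "successes", "n_shots")]
    stages[[k]]$lambda <- lams[k + 1]
    if (st$halted) { halted <- TRUE; break }
    states <- st$states
    if (keep_states) stage_states[[k + 1]] <- states
  }
  structure(list(flux = flux[c("phi0", "se", "n_crossings", "time")],
                 stages = stages[!vapply(stages, is.null, TRUE)],
                 final_states = states, stage_states = stage_states,
                 interfaces = interfaces,
                 halted = halted, seed = seed,
                 conditions = sim$conditions), class = "ffs_run")
}

#' Staged hybridization FFS campaign for a strand pair
#'
#' Convenience wrapper that builds a separated-strand starting state,
#' defines the staged interfaces (interstrand contact, one base pair, two
#' base pairs, then the duplex criterion or a first-structure criterion of
#' `n_target` base pairs) and runs direct FFS. The default duplex
#' criterion is N - 2 base pairs: a duplex with at most two frayed
#' terminal pairs is committed to the bound basin, whereas demanding all N
#' pairs simultaneously would make the target depend on end breathing.
#' For repetitive sequences, set `count = "total"` and a small `n_target`
#' to measure the rate into a first misaligned structure instead.
#'
#' @param sequences two-strand character vector or preset name
#' @param temperature kelvin
#' @param box cubic box edge (sets the strand-pair concentration)
#' @param params a `model_parameters` object
#' @param thermo a `thermostat_settings` object
#' @param n_target base pairs defining the final interface (default:
#'   N - 2, the duplex criterion)
#' @param count `"native"` or `"total"` base pairs in the staged order
#'   parameter
#' @param n_shots,min_crossings,max_steps_flux,max_steps_shot FFS controls
#' @param seed RNG seed
#' @param keep_states retain the interface state ensembles
#' @return an `ffs_run`
#' @export
hybridization_ffs <- function(sequences, temperature, box,
                              params = load_parameters("average"),
                              thermo = thermostat_settings("langevin"),
                              n_target = NULL, count = "total",
                              n_shots = 50, min_crossings = 30,
                              max_steps_flux = 5e6, max_steps_shot = 1e6,
                              seed = 1, keep_states = TRUE) {
  cfg <- build_configuration(sequences, "separated_strands", box = box,
                             temperature = temperature, params = params,
                             seed = seed)
  N <- nchar(cfg$seqs[1])
  if (is.null(n_target)) n_target <- max(2L, N - 2L)
  spec <- order_parameter_spec(n_target, params, count = count)
  sim <- dna_ffs_sim(cfg, params, thermo, spec)
  ifs <- interface_set(c(1, 2, 3, 1 + n_target))
  run_ffs(sim, ifs, n_shots = n_shots, min_crossings = min_crossings,
          max_steps_flux = max_steps_flux, max_steps_shot = max_steps_shot,
          seed = seed, keep_states = keep_states)
}

#' Compose the FFS rate estimate
#'
#' k = Phi0 * prod(p_i), with the standard error propagated in relative
#' terms (Poisson flux, binomial stages) and a parametric-bootstrap CI.
#'
#' @param run an `ffs_run` record
#' @param n_boot bootstrap replicates for the CI
#' @return an `ffs_rate` with `k`, `se`, `ci`, per-stage quantities
#' @export
estimate_rate <- function(run, n_boot = 2000) {
  if (!inherits(run, "ffs_run")) stop("need an ffs_run record")
  if (run$halted)
    stop("incomplete run: an interface stage had zero successes; ",
         "no rate can be composed")
  n_stage <- length(run$interfaces$lambdas) - 1
  if (length(run$stages) < n_stage)
    stop("incomplete run: missing interface stages ",
         paste(seq(length(run$stages) + 1, n_stage), collapse = ", "))
  p <- vapply(run$stages, function(s) s$p, 0)
  k <- run$flux$phi0 * prod(p)
  rel2 <- (run$flux$se / run$flux$phi0)^2 +
    sum(vapply(run$stages, function(s)
      if (s$p > 0) s$se^2 / s$p^2 else 0, 0))
  # parametric bootstrap: Poisson crossings, binomial stage successes
  nc <- run$flux$n_crossings
  boot <- replicate(n_boot, {
    phi_b <- stats::rpois(1, nc) / run$flux$time
    pb <- vapply(run$stages, function(s)
      stats::rbinom(1, s$n_shots, s$p) / s$n_shots, 0)
    phi_b * prod(pb)
  })
  structure(list(k = k, se = k * sqrt(rel2),
                 ci = unname(quantile(boot, c(0.025, 0.975))),
                 phi0 = run$flux$phi0, p = p,
                 p_se = vapply(run$stages, function(s) s$se, 0),
                 boot = boot, conditions = run$conditions,
                 seed = run$seed), class = "ffs_rate")
}

#' @export
print.ffs_rate <- function(x, ...) {
  cat("<ffs_rate> k =", signif(x$k, 4), "+/-", signif(x$se, 2),
      "per time unit\n")
  cat("  phi0 =", signif(x$phi0, 4), "; p =",
      paste(signif(x$p, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Bimolecular rate constant from a per-pair association rate
#'
#' Converts a first-order rate (events per simulation time for one strand
#' pair in the box) to a bimolecular constant k * V * N_A in M^-1 per
#' simulation time unit.
#'
#' @param rate an `ffs_rate` or numeric rate
#' @param box cubic box edge (simulation length units)
#' @param params a `model_parameters` object
#' @export
bimolecular_rate <- function(rate, box, params) {
  k <- if (inherits(rate, "ffs_rate")) rate$k else rate
  k / box_concentration(box, params)
}

#' Commitment probability to the full duplex
#'
#' Fraction of unbiased continuations from a stated interface ensemble that
#' reach the target (full-duplex) interface before returning to the unbound
#' basin.
#'
#' @param states list of states drawn from an interface ensemble
#' @param sim an `ffs_sim`
#' @param lambda_target the full-duplex criterion
#' @param n_shots number of continuations
#' @param max_steps per-shot budget
#' @param seed RNG seed
#' @return list with `p`, `se`, `successes`, `n_shots`
#' @export
commit_probability <- function(states, sim, lambda_target, n_shots = 100,
                               max_steps = 1e6, seed = 1) {
  set.seed(seed)
  already <- vapply(states, function(s) sim$lambda(s) >= lambda_target, TRUE)
  if (all(already))
    return(list(p = 1.0, se = 0.0, successes = as.integer(n_shots),
                n_shots = as.integer(n_shots)))
  st <- shoot_interface(states, sim, lambda_target, n_shots, max_steps)
  st[c("p", "se", "successes", "n_shots")]
}
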