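# Time evolution: rigid-body Langevin and Brownian dynamics.

#' Thermostat settings
#'
#' The Langevin scheme integrates inertial rigid-body motion with drag and
#' Gaussian noise balanced to sample the canonical ensemble (BAOAB
#' splitting; the friction implied by a translational/rotational diffusion
#' coefficient is gamma = kT / D at the run temperature). The Brownian
#' scheme is the overdamped Euler-Maruyama limit and is conventionally run
#' with a larger effective diffusion coefficient. `diffusion_scale`
#' multiplies both diffusion coefficients and is recorded so that only
#' rates computed at equal scales are compared.
#'
#' @param scheme `"langevin"` or `"brownian"`
#' @param D_t,D_r translational and rotational diffusion coefficients
#'   (simulation units)
#' @param dt integration timestep (simulation time units)
#' @param diffusion_scale dimensionless acceleration factor applied to both
#'   diffusion coefficients
#' @param gamma_t,gamma_r optional explicit friction constants; required at
#'   zero temperature where gamma = kT/D is undefined (zero friction gives
#'   plain symplectic rigid-body dynamics)
#' @export
thermostat_settings <- function(scheme = c("langevin", "brownian"),
                                D_t = 1.0, D_r = 3.0, dt = 0.005,
                                diffusion_scale = 1.0,
                                gamma_t = NULL, gamma_r = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(D_t > 0, D_r > 0, dt > 0, diffusion_scale > 0)
  structure(list(scheme = scheme, D_t = D_t, D_r = D_r, dt = dt,
                 diffusion_scale = diffusion_scale,
                 gamma_t = gamma_t, gamma_r = gamma_r),
            class = "thermostat_settings")
}

# resolve the C++ thermostat list at a given thermal energy
.thermo_cpp <- function(thermo, kT) {
  Dt <- thermo$D_t * thermo$diffusion_scale
  Dr <- thermo$D_r * thermo$diffusion_scale
  gt <- thermo$gamma_t
  gr <- thermo$gamma_r
  if (is.null(gt)) {
    if (kT <= 0 && thermo$scheme == "langevin")
      gt <- 0  # zero temperature without explicit friction: pure Hamiltonian
    else gt <- kT / Dt
  }
  if (is.null(gr)) gr <- if (kT <= 0) 0 else kT / Dr
  if (thermo$scheme == "brownian" && kT <= 0)
    stop("the Brownian scheme requires temperature > 0")
  list(scheme = if (thermo$scheme == "langevin") 0L else 1L,
       dt = thermo$dt, Dt = Dt, Dr = Dr, gamma_t = gt, gamma_r = gr)
}

#' Evolve a configuration in time
#'
#' Propagates the system for `n_steps` with the chosen thermostat, emitting
#' trajectory frames every `stride` steps. Propagation is bitwise
#' reproducible for a fixed seed. A numerical blow-up (non-finite energy or
#' runaway force) aborts with an error.
#'
#' @param config a `dna_config`
#' @param params a `model_parameters` object
#' @param thermo a `thermostat_settings` object
#' @param n_steps number of integration steps (>= 1)
#' @param stride energy/frame sampling interval in steps (0: final state only)
#' @param store_frames keep full trajectory frames (poses and momenta)
#' @param seed optional RNG seed set before propagation
#' @return list with `config` (final state), `energies` (data frame of
#'   step, potential and kinetic energy) and `frames` (list of state lists)
#' @export
evolve <- function(config, params, thermo, n_steps, stride = 0,
                   store_frames = FALSE, seed = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  kT <- sim_kT(config$temperature, params)
  res <- do.call(cpp_sim_run, c(
    .cpp_args(config, params),
    list(thermo = .thermo_cpp(thermo, kT), nsteps = as.integer(n_steps),
         stride = as.integer(stride), store_frames = store_frames)))
  en <- as.data.frame(res$energies)
  en$total <- en$epot + en$ekin
  list(config = .set_state(config, res$state), energies = en,
       frames = res$frames)
}
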