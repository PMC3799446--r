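# Toy oracle systems with independently computable reference observables,
# used to validate the Monte Carlo, umbrella-sampling and forward-flux
# machinery against quadrature and brute-force simulation.

#' Metropolis acceptance probability
#'
#' The acceptance rule shared by every Monte Carlo sampler in the package:
#' min(1, weight_ratio * exp(-dE / kT)). Exposed so detailed-balance audits
#' can check logged proposals against the rule.
#'
#' @param dE proposed energy change
#' @param kT thermal energy
#' @param weight_ratio umbrella-weight ratio w(new) / w(old)
#' @export
mc_accept_prob <- function(dE, kT, weight_ratio = 1) {
  pmin(1, weight_ratio * exp(-dE / kT))
}

#' Build a toy oracle system
#'
#' Two kinds are provided. `double_well_walker`: an overdamped 1D walker in
#' V(x) = h (x^2 - 1)^2 + tilt * x, the oracle substrate for forward flux
#' sampling (its transition rate is measurable by brute force and its well
#' occupancies by quadrature). `two_state_dimer`: the radial coordinate of
#' a particle pair with a short-range isotropic attraction
#' V(r) = -eps (1 - (r/rc)^2)^2 inside r < rc, with the 3D r^2 measure and
#' a reflecting outer wall at `rmax`; its bound/unbound free-energy
#' difference and equilibrium constant follow from a configurational
#' integral, and binding/unbinding rates are measurable directly.
#'
#' @param kind `"double_well_walker"` or `"two_state_dimer"`
#' @param parameters named list overriding the defaults (h, tilt, eps, rc,
#'   rmin, rmax, kT, D, dt)
#' @return a `toy_system`
#' @export
make_toy <- function(kind = c("double_well_walker", "two_state_dimer"),
                     parameters = list()) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown toy kind: ", kind[1],
                                            call. = FALSE))
  defaults <- if (kind == "double_well_walker") {
    list(pot_id = 0L, h = 0.4, tilt = 0, eps = 0, rc = 1, rmin = -Inf,
         rmax = Inf, kT = 0.1, D = 1, dt = 1e-3)
  } else {
    list(pot_id = 1L, h = 0, tilt = 0, eps = 0.3, rc = 0.5, rmin = 0.05,
         rmax = 3, kT = 0.1, D = 1, dt = 1e-4)
  }
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown) > 0)
    stop("unknown toy parameter(s): ", paste(unknown, collapse = ", "))
  wpar <- utils::modifyList(defaults, parameters)
  toy <- if (kind == "double_well_walker") {
    list(kind = kind, wpar = wpar, x0 = -1, xsplit = 0,
         basin = -0.9, target = 0.9, lam0 = -0.6,
         qlim = c(-3, 3))
  } else {
    list(kind = kind, wpar = wpar, x0 = wpar$rc / 2, xsplit = wpar$rc,
         basin = wpar$rc * 0.6, target = wpar$rmax * 0.9,
         lam0 = wpar$rc * 1.4, qlim = c(wpar$rmin, wpar$rmax))
  }
  structure(toy, class = "toy_system")
}

#' Toy potential energy
#' @param toy a `toy_system`
#' @param x coordinate (vectorized)
#' @export
toy_potential <- function(toy, x) {
  w <- toy$wpar
  if (toy$kind == "double_well_walker") {
    w$h * (x^2 - 1)^2 + w$tilt * x
  } else {
    ifelse(x < w$rc, -w$eps * (1 - (x / w$rc)^2)^2, 0)
  }
}

# unnormalized stationary density (includes the r^2 measure for the dimer)
.toy_density <- function(toy, x) {
  d <- exp(-toy_potential(toy, x) / toy$wpar$kT)
  if (toy$kind == "two_state_dimer") d <- d * x^2
  d
}

#' Quadrature occupancy of the left/bound state
#'
#' Probability of x < xsplit under the exact stationary distribution,
#' computed by numerical integration (the independent oracle for the
#' samplers).
#'
#' @param toy a `toy_system`
#' @param xsplit state boundary (defaults to the toy's own)
#' @export
toy_occupancy_quadrature <- function(toy, xsplit = toy$xsplit) {
  lo <- toy$qlim[1]; hi <- toy$qlim[2]
  za <- integrate(function(x) .toy_density(toy, x), lo, xsplit,
                  rel.tol = 1e-10)$value
  zb <- integrate(function(x) .toy_density(toy, x), xsplit, hi,
                  rel.tol = 1e-10)$value
  za / (za + zb)
}

#' Exact free-energy difference between the two toy states
#'
#' F(x >= xsplit) - F(x < xsplit) in units of kT, by quadrature.
#' @param toy a `toy_system`
#' @param xsplit state boundary
#' @export
toy_deltaF_quadrature <- function(toy, xsplit = toy$xsplit) {
  p <- toy_occupancy_quadrature(toy, xsplit)
  -log((1 - p) / p)
}

#' Dimer equilibrium constant K = P_bound / P_unbound by quadrature
#' @param toy a `two_state_dimer` toy
#' @export
toy_Keq_quadrature <- function(toy) {
  stopifnot(toy$kind == "two_state_dimer")
  p <- toy_occupancy_quadrature(toy, toy$wpar$rc)
  p / (1 - p)
}

#' Sampled occupancy of the left/bound state with block errors
#'
#' @param toy a `toy_system`
#' @param nsteps total walker steps
#' @param blocks number of sequential blocks for the SE
#' @param xsplit state boundary
#' @param burn discarded initial steps
#' @return list with `occupancy`, `se`, `blocks`
#' @export
toy_occupancy <- function(toy, nsteps = 2e6, blocks = 10,
                          xsplit = toy$xsplit, burn = nsteps / 20) {
  per <- floor((nsteps - burn) / blocks)
  r <- cpp_walker_occupancy(toy$x0, toy$wpar, xsplit, as.numeric(burn), 0)
  x <- r$x
  occ <- numeric(blocks)
  for (b in seq_len(blocks)) {
    r <- cpp_walker_occupancy(x, toy$wpar, xsplit, as.numeric(per), 0)
    occ[b] <- r$occupancy
    x <- r$x
  }
  list(occupancy = mean(occ), se = sd(occ) / sqrt(blocks), blocks = occ)
}

#' Brute-force transition rate of a toy system
#'
#' Long unbiased run; transitions to `target` are counted per unit time
#' attached to the starting basin (the same normalization as the FFS
#' estimate), with the basin re-armed at `rearm`.
#'
#' @param toy a `toy_system`
#' @param nsteps walker steps
#' @param x0 starting coordinate (defaults to the toy basin)
#' @param target absorbing-side threshold
#' @param rearm coordinate that re-attaches the trajectory to the basin
#' @return list with `k`, `se` (Poisson), `n_transitions`, `time_in_basin`
#' @export
toy_brute_rate <- function(toy, nsteps = 5e6, x0 = toy$x0,
                           target = toy$target, rearm = toy$basin) {
  direction <- if (target >= x0) 1L else -1L
  r <- cpp_walker_brute_rate(x0, toy$wpar, rearm, target, rearm,
                             as.numeric(nsteps), direction)
  if (r$n_transitions == 0)
    stop("no transitions observed in ", nsteps, " steps")
  k <- r$n_transitions / r$time_in_A
  list(k = k, se = k / sqrt(r$n_transitions),
       n_transitions = r$n_transitions, time_in_basin = r$time_in_A)
}

#' Metropolis sampling of a toy system with umbrella weights
#'
#' R-level Metropolis chain targeting the toy's stationary distribution
#' times a two-state umbrella weight, using [mc_accept_prob()]. Returns
#' block-wise state counts for reweighting and error estimation.
#'
#' @param toy a `toy_system`
#' @param nsteps Metropolis steps
#' @param weights length-2 positive weights (state 1: x < xsplit, state 2:
#'   x >= xsplit)
#' @param sd_prop proposal standard deviation
#' @param blocks sequential blocks
#' @param burn discarded initial steps
#' @return list with `counts` (2-vector), `block_counts` (blocks x 2),
#'   `occupancy` (reweighted bound-state estimate), `se`
#' @export
toy_mc_umbrella <- function(toy, nsteps = 1e5, weights = c(1, 1),
                            sd_prop = 0.15, blocks = 10, burn = nsteps / 10) {
  stopifnot(length(weights) == 2, all(weights > 0))
  w <- toy$wpar
  state_of <- function(x) if (x < toy$xsplit) 1L else 2L
  lo <- max(toy$qlim[1], -1e6); hi <- min(toy$qlim[2], 1e6)
  x <- toy$x0
  s <- state_of(x)
  bc <- matrix(0, blocks, 2)
  per <- floor((nsteps - burn) / blocks)
  total <- burn + per * blocks
  for (step in seq_len(total)) {
    xp <- x + rnorm(1, sd = sd_prop)
    if (xp >= lo && xp <= hi) {
      sp <- state_of(xp)
      dE <- toy_potential(toy, xp) - toy_potential(toy, x)
      wr <- weights[sp] / weights[s]
      # the r^2 measure enters as an effective log-weight for the dimer
      if (toy$kind == "two_state_dimer") wr <- wr * (xp / x)^2
      if (runif(1) < mc_accept_prob(dE, w$kT, wr)) { x <- xp; s <- sp }
    }
    if (step > burn) {
      b <- ((step - burn - 1) %/% per) + 1
      bc[b, s] <- bc[b, s] + 1
    }
  }
  counts <- colSums(bc)
  occ_blocks <- apply(bc, 1, function(cb) reweight_histogram(cb, weights)[1])
  list(counts = counts, block_counts = bc,
       occupancy = reweight_histogram(counts, weights)[1],
       se = sd(occ_blocks) / sqrt(blocks))
}
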