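# Potential energy, forces and torques.

.energy_report <- function(terms, total) {
  structure(list(terms = terms, total = total), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report> total =", format(x$total, digits = 6), "\n")
  print(round(x$terms, 6))
  invisible(x)
}

#' Interaction energy of a single nucleotide pair
#'
#' Per-term energies (backbone, hydrogen bonding, stacking, cross-stacking,
#' coaxial stacking, excluded volume) between nucleotides `i` and `j`
#' (global 0-based indices). The backbone term is present only for bonded
#' neighbours; hydrogen bonding is nonzero only for Watson-Crick identities
#' within range and favourable alignment; every term vanishes beyond its
#' cutoff; the report is symmetric under swapping `i` and `j`. Site-site
#' vectors use the minimum-image convention.
#'
#' @param config a `dna_config`
#' @param params a `model_parameters` object
#' @param i,j global nucleotide indices (0-based)
#' @return an `energy_report`
#' @export
pair_energy <- function(config, params, i, j) {
  n <- length(config$base)
  if (i == j) stop("pair_energy requires i != j")
  if (i < 0 || j < 0 || i >= n || j >= n)
    stop("nucleotide index out of range [0, ", n - 1, "]")
  res <- do.call(cpp_pair_energy,
                 c(.cpp_args(config, params), list(i = i, j = j)))
  .energy_report(res$terms, res$total)
}

#' Total potential energy, forces and torques
#'
#' Evaluates the full potential and, when `gradients = TRUE`, the analytic
#' forces and body torques (the negative gradient of the potential with
#' respect to rigid-body pose). The energy is invariant under global
#' translation and rotation; for an isolated system the forces sum to zero
#' and the total torque about any point vanishes.
#'
#' @param config a `dna_config`
#' @param params a `model_parameters` object
#' @param gradients also compute forces and torques
#' @return list with `energy` (an `energy_report`) and, with gradients,
#'   `force` and `torque` (N x 3 matrices)
#' @export
total_energy <- function(config, params, gradients = FALSE) {
  if (!.frame_ok(config$a1, config$a3)) stop("non-orthonormal frame")
  res <- do.call(cpp_energy, c(.cpp_args(config, params),
                               list(grad = gradients)))
  out <- list(energy = .energy_report(res$terms, res$total))
  if (gradients) { out$force <- res$force; out$torque <- res$torque }
  out
}

#' @rdname total_energy
#' @export
forces_torques <- function(config, params) {
  res <- total_energy(config, params, gradients = TRUE)
  list(force = res$force, torque = res$torque, energy = res$energy)
}
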