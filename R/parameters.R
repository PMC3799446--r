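# Model parameterization: loading, validation, unit conversions.

.param_schema_version <- 1

# every key the packaged tables must provide, with admissible ranges
.param_schema <- list(
  pos_back = c(-1, 0), pos_stack = c(0, 1), pos_hb = c(0, 1),
  fene_eps = c(1e-8, Inf), fene_r0 = c(1e-8, Inf), fene_delta = c(1e-8, Inf),
  exc_eps = c(0, Inf), sig_bb = c(1e-8, Inf), sig_bs = c(1e-8, Inf),
  sig_ss = c(1e-8, Inf), sig_bonded = c(1e-8, Inf),
  hb_r0 = c(0, Inf), hb_wr = c(1e-8, Inf), hb_w1 = c(1e-8, 2), hb_w2 = c(1e-8, 2),
  hb_eps_at = c(0, Inf), hb_eps_gc = c(0, Inf),
  st_r0 = c(0, Inf), st_wr = c(1e-8, Inf), st_w1 = c(1e-8, 2),
  st_cref2 = c(0, 1), st_w2 = c(1e-8, 2),
  st_eta = c(0, Inf), st_alpha = c(0, Inf),
  st_g_a = c(0, Inf), st_g_c = c(0, Inf), st_g_g = c(0, Inf), st_g_t = c(0, Inf),
  cx_eps = c(0, Inf), cx_r0 = c(0, Inf), cx_wr = c(1e-8, Inf), cx_w1 = c(1e-8, 2),
  coax_on = c(0, 1), coax_eps = c(0, Inf), coax_r0 = c(0, Inf),
  coax_wr = c(1e-8, Inf), coax_w1 = c(1e-8, 2),
  sim_length_nm = c(1e-8, Inf), sim_energy_kcal_mol = c(1e-8, Inf),
  sim_temp_K = c(1e-8, Inf),
  hb_pair_frac = c(1e-8, 1), st_pair_frac = c(1e-8, 1),
  helix_rise = c(1e-8, Inf), helix_twist_deg = c(-360, 360),
  helix_r_hb = c(0, Inf)
)

.bases <- c("A", "C", "G", "T")

#' Load a model parameterization
#'
#' Reads one of the packaged parameter tables (key-value TSV with a schema
#' version) and returns a validated `model_parameters` object. The `average`
#' variant has base-independent hydrogen-bonding and stacking strengths;
#' in the `sequence_dependent` variant those strengths depend on base
#' identity (G-C pairs stronger than A-T). Hydrogen bonding is nonzero only
#' between Watson-Crick complementary bases in either variant. Backbone and
#' excluded-volume constants are identical across variants.
#'
#' @param variant `"average"` or `"sequence_dependent"`.
#' @param file optional path to a parameter table following the packaged
#'   schema (defaults to the table shipped with the package).
#' @return an object of class `model_parameters`.
#' @export
load_parameters <- function(variant = c("average", "sequence_dependent"),
                            file = NULL) {
  variant <- tryCatch(match.arg(variant),
                      error = function(e) stop("unknown parameterization variant: ",
                                               variant[1], call. = FALSE))
  if (is.null(file)) {
    fname <- if (variant == "average") "model_params_average.tsv" else "model_params_seqdep.tsv"
    file <- system.file("extdata", fname, package = "hybridkin", mustWork = TRUE)
  }
  raw <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(raw)))
    stop("parameter table must have columns 'key' and 'value'")
  tab <- setNames(raw$value, raw$key)

  if (!"schema_version" %in% names(tab))
    stop("parameter schema error: missing field 'schema_version'")
  if (as.numeric(tab[["schema_version"]]) != .param_schema_version)
    stop("parameter schema error: unsupported schema_version ",
         tab[["schema_version"]])
  if (!"variant" %in% names(tab))
    stop("parameter schema error: missing field 'variant'")
  if (tab[["variant"]] != variant)
    stop("parameter table declares variant '", tab[["variant"]],
         "' but '", variant, "' was requested")

  vals <- list()
  for (key in names(.param_schema)) {
    if (!key %in% names(tab))
      stop("parameter schema error: missing field '", key, "'")
    v <- suppressWarnings(as.numeric(tab[[key]]))
    if (is.na(v))
      stop("parameter schema error: field '", key, "' is not numeric")
    rng <- .param_schema[[key]]
    if (v < rng[1] || v > rng[2])
      stop("parameter schema error: field '", key, "' = ", v,
           " outside admissible range [", rng[1], ", ", rng[2], "]")
    vals[[key]] <- v
  }

  # hydrogen-bond strength matrix: nonzero ONLY for Watson-Crick identities
  hb <- matrix(0, 4, 4, dimnames = list(.bases, .bases))
  hb["A", "T"] <- hb["T", "A"] <- vals$hb_eps_at
  hb["C", "G"] <- hb["G", "C"] <- vals$hb_eps_gc
  g <- c(A = vals$st_g_a, C = vals$st_g_c, G = vals$st_g_g, T = vals$st_g_t)
  sf <- outer(g, g)

  cpp <- vals[c("pos_back", "pos_stack", "pos_hb", "fene_eps", "fene_r0",
                "fene_delta", "exc_eps", "sig_bb", "sig_bs", "sig_ss",
                "sig_bonded", "hb_r0", "hb_wr", "hb_w1", "hb_w2",
                "st_r0", "st_wr", "st_w1", "st_cref2", "st_w2",
                "st_eta", "st_alpha", "cx_eps", "cx_r0", "cx_wr", "cx_w1",
                "coax_eps", "coax_r0", "coax_wr", "coax_w1")]
  cpp$coax_on <- vals$coax_on > 0
  cpp$native_only <- FALSE
  cpp$hb_eps_mat <- hb
  cpp$st_fac_mat <- sf

  structure(list(
    variant = variant,
    values = vals,
    cpp = cpp,
    units = list(length_nm = vals$sim_length_nm,
                 energy_kcal_mol = vals$sim_energy_kcal_mol,
                 temp_K = vals$sim_temp_K),
    helix = list(rise = vals$helix_rise,
                 twist = vals$helix_twist_deg * pi / 180,
                 r_hb = vals$helix_r_hb,
                 r_com = vals$helix_r_hb + vals$pos_hb),
    source = file
  ), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>", x$variant, "variant\n")
  cat("  HB strengths: A-T", x$values$hb_eps_at, ", G-C", x$values$hb_eps_gc,
      "(simulation energy units)\n")
  cat("  coaxial stacking:", if (x$cpp$coax_on) "on" else "off",
      "; native-only hydrogen bonding:", x$cpp$native_only, "\n")
  cat("  units: 1 length =", x$units$length_nm, "nm; 1 energy =",
      x$units$energy_kcal_mol, "kcal/mol; kT = T /", x$units$temp_K, "\n")
  invisible(x)
}

#' Thermal energy in simulation units at a temperature in kelvin
#' @param temperature temperature in kelvin
#' @param params a `model_parameters` object
#' @export
sim_kT <- function(temperature, params) temperature / params$units$temp_K

#' Restrict hydrogen bonding to native base pairs
#'
#' Returns a copy of `params` in which only native base pairs (as recorded in
#' a configuration's native-partner map) carry a nonzero hydrogen-bonding
#' energy. Used to suppress misaligned bonding and internal displacement.
#'
#' @param params a `model_parameters` object
#' @param native_only logical switch
#' @export
set_native_only <- function(params, native_only = TRUE) {
  stopifnot(inherits(params, "model_parameters"))
  params$cpp$native_only <- isTRUE(native_only)
  params
}

#' Enable or disable the coaxial-stacking model-family term
#' @param params a `model_parameters` object
#' @param on logical switch
#' @export
set_coaxial <- function(params, on = TRUE) {
  stopifnot(inherits(params, "model_parameters"))
  params$cpp$coax_on <- isTRUE(on)
  params
}

# typical full hydrogen-bond depth (simulation units) for the variant
.typical_hb_depth <- function(params) {
  mean(c(params$values$hb_eps_at, params$values$hb_eps_gc))
}

#' Default base-pairing energy threshold
#'
#' A base pair is counted when its hydrogen-bond term is at or below this
#' threshold, a fixed fraction of the typical full hydrogen-bond depth.
#' @param params a `model_parameters` object
#' @return negative energy threshold in simulation units
#' @export
pairing_threshold <- function(params) {
  -params$values$hb_pair_frac * .typical_hb_depth(params)
}

# stacking detection threshold (same convention as base pairing)
.stacking_threshold <- function(params, temperature) {
  kT <- sim_kT(temperature, params)
  -params$values$st_pair_frac * (params$values$st_eta + params$values$st_alpha * kT)
}

#' Convert simulation energies to kcal/mol
#' @param e energy in simulation units
#' @param params a `model_parameters` object
#' @export
to_kcal_mol <- function(e, params) e * params$units$energy_kcal_mol

#' Convert simulation lengths to nanometres
#' @param x length in simulation units
#' @param params a `model_parameters` object
#' @export
to_nm <- function(x, params) x * params$units$length_nm
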