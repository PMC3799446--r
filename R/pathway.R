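# Hybridization-pathway analysis: mechanism classification, kinetic vs
# equilibrium ensemble comparison, Arrhenius analysis, relative rates.

# frame label from a secondary structure:
#   "unbound", "register:<r>", "bulge:<r1>+<r2>" (two coexisting registers,
#   monotonic mapping), "pseudoknot:<r1>,<r2>", "full_duplex"
.frame_label <- function(struct) {
  if (struct$n_total == 0) return("unbound")
  if (struct$n_native == struct$n) return("full_duplex")
  if (!is.null(struct$pseudoknot))
    return(paste0("pseudoknot:", paste(struct$pseudoknot, collapse = ",")))
  regs <- sort(unique(struct$pairs$register))
  if (length(regs) >= 2) {
    h <- struct$register_hist
    top <- as.integer(names(sort(h, decreasing = TRUE)))[1:2]
    return(paste0("bulge:", paste(sort(top, decreasing = TRUE),
                                  collapse = "+")))
  }
  paste0("register:", regs)
}

#' Assemble a transition record from a structure sequence
#'
#' @param structures time-ordered list of `secondary_structure` frames
#' @return a `transition_record`
#' @export
transition_record <- function(structures) {
  labels <- vapply(structures, .frame_label, "")
  structure(list(structures = structures, labels = labels),
            class = "transition_record")
}

# run-length encode labels, drop runs shorter than dwell_min, merge
.dwelled_labels <- function(labels, dwell_min) {
  r <- rle(labels)
  keep <- r$lengths >= dwell_min
  if (!any(keep)) return(character(0))
  lab <- r$values[keep]
  # merge adjacent repeats created by dropping flickers
  if (length(lab) > 1) {
    lab <- lab[c(TRUE, lab[-1] != lab[-length(lab)])]
  }
  lab
}

#' Classify a hybridization/rearrangement trajectory
#'
#' The mechanism is a deterministic function of the coarse structure
#' sequence: `zippering` when a single register grows to completion with no
#' dwelled alternative-register or pseudoknot intermediates; `inchworm` when
#' two registers coexist as a dwelled bulge (monotonic partner mapping) and
#' the new register displaces the old; `pseudoknot_displacement` when a
#' dwelled non-monotonic (pseudoknot) intermediate occurs between the start
#' and end structures; `detachment` when the record ends unbound; `mixed`
#' when several displacement mechanisms occur (the ordered list is
#' recorded; the headline label is the first displacement mechanism).
#' States dwelled for fewer than `dwell_min` frames are treated as flickers
#' and ignored.
#'
#' @param record a `transition_record` (or list of `secondary_structure`)
#' @param dwell_min minimum frames for a state to count as dwelled
#' @return list with `mechanism`, `mechanisms` (ordered), `start`, `end`,
#'   `dwelled` (the dwelled label sequence)
#' @export
classify_transition <- function(record, dwell_min = 10) {
  if (!inherits(record, "transition_record"))
    record <- transition_record(record)
  lab <- .dwelled_labels(record$labels, dwell_min)
  if (length(lab) < 2)
    stop("open record: fewer than two dwelled states between start and ",
         "an absorbing end")
  start <- lab[1]; end <- lab[length(lab)]
  mid <- lab[-c(1, length(lab))]
  mechs <- character(0)
  for (l in lab[-1]) {
    if (startsWith(l, "pseudoknot:")) mechs <- c(mechs, "pseudoknot_displacement")
    if (startsWith(l, "bulge:")) mechs <- c(mechs, "inchworm")
  }
  mechs <- mechs[!duplicated(mechs)]
  # a register change without any dwelled two-register intermediate still
  # proceeded through displacement; attribute it to the flickering kind if
  # unseen, otherwise keep the observed order
  headline <- if (end == "unbound") {
    "detachment"
  } else if (length(mechs) == 0) {
    regs <- grep("^register:|^full_duplex$", lab, value = TRUE)
    regs <- setdiff(unique(sub("full_duplex", "register:0", regs)), character(0))
    if (length(regs) <= 1) "zippering" else "mixed"
  } else if (length(mechs) == 1) {
    mechs
  } else {
    "mixed"
  }
  list(mechanism = headline, mechanisms = mechs, start = start, end = end,
       dwelled = lab)
}

#' Mechanism census over many trajectories
#'
#' @param records list of `transition_record`s
#' @param dwell_min as in [classify_transition()]
#' @return data frame: start, end, mechanism, count
#' @export
mechanism_census <- function(records, dwell_min = 10) {
  rows <- lapply(records, function(r) {
    cl <- classify_transition(r, dwell_min)
    data.frame(start = cl$start, end = cl$end, mechanism = cl$mechanism)
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1, nrow(df))),
                          by = df[c("start", "end", "mechanism")], FUN = sum)
  agg[order(-agg$count), ]
}

#' Compare kinetic and equilibrium ensembles at matched base pairing
#'
#' Both ensembles must be conditioned on the same base-pair count n. For
#' each state the per-base separation between a base's hydrogen-bonding
#' site and that of its native partner is averaged over bases; intrastrand
#' stacking is counted through the stacking-term threshold. Standard errors
#' come from a state-level bootstrap.
#'
#' @param kinetic,equilibrium lists of `dna_config` states conditioned on n
#' @param n the matched base-pair count
#' @param params a `model_parameters` object
#' @param n_boot bootstrap replicates
#' @return an `ensemble_comparison` data frame (one row per ensemble) with
#'   mean native-partner separation (nm), mean intrastrand stacking count,
#'   and their bootstrap SEs
#' @export
ensemble_compare <- function(kinetic, equilibrium, n, params, n_boot = 500) {
  if (length(kinetic) == 0 || length(equilibrium) == 0)
    stop("both ensembles must be non-empty")
  study <- function(cfgs, label) {
    stats_one <- function(cfg) {
      ss <- detect_base_pairs(cfg, params)
      if (ss$n_total != n)
        stop("conditioning error: a ", label, " state has ", ss$n_total,
             " base pairs, expected ", n)
      # per-base distance to the native partner's hydrogen-bonding site
      hb_site <- cfg$com + params$values$pos_hb * cfg$a1
      ok <- cfg$nat >= 0
      d <- hb_site[ok, , drop = FALSE] - hb_site[cfg$nat[ok] + 1, , drop = FALSE]
      d <- d - cfg$box * round(d / cfg$box)
      sep_nm <- mean(sqrt(rowSums(d^2))) * params$units$length_nm
      sm <- do.call(cpp_stack_energies, .cpp_args(cfg, params))
      thr <- .stacking_threshold(params, cfg$temperature)
      c(sep = sep_nm, stack = sum(sm[, 3] <= thr))
    }
    per_state <- t(vapply(cfgs, stats_one, c(sep = 0, stack = 0)))
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(per_state), replace = TRUE)
      colMeans(per_state[idx, , drop = FALSE])
    })
    data.frame(ensemble = label, n = n, n_states = nrow(per_state),
               separation_nm = mean(per_state[, "sep"]),
               separation_se = sd(boots["sep", ]),
               stacking = mean(per_state[, "stack"]),
               stacking_se = sd(boots["stack", ]))
  }
  out <- rbind(study(kinetic, "kinetic"), study(equilibrium, "equilibrium"))
  class(out) <- c("ensemble_comparison", "data.frame")
  out
}

# gas constant in kcal/(mol K)
.R_KCAL <- 0.0019872041

#' Apparent activation enthalpy from a rate-temperature series
#'
#' For each adjacent temperature pair the apparent activation enthalpy is
#' the finite-difference Arrhenius slope
#' dH = -R * (ln k2 - ln k1) / (1/T2 - 1/T1), in kcal/mol; a rate series
#' following k = k0 exp(-dH / R T) with constant dH is recovered exactly.
#' Negative values mean the rate falls as temperature rises.
#'
#' @param temperatures temperatures in kelvin (>= 2, distinct)
#' @param rates positive rates (any common relative scale)
#' @param se optional standard errors of the rates
#' @return an `arrhenius_fit`: data frame with T1, T2, T_mid, dH_kcal,
#'   se_kcal
#' @export
arrhenius_apparent_enthalpy <- function(temperatures, rates, se = NULL) {
  stopifnot(length(temperatures) == length(rates))
  if (length(temperatures) < 2)
    stop("need at least two temperatures")
  if (any(rates <= 0)) stop("rates must be positive")
  if (any(duplicated(temperatures)))
    stop("apparent activation enthalpy is defined only between distinct ",
         "temperatures")
  o <- order(temperatures)
  temperatures <- temperatures[o]; rates <- rates[o]
  if (!is.null(se)) se <- se[o]
  i <- seq_len(length(rates) - 1)
  dinv <- 1 / temperatures[i + 1] - 1 / temperatures[i]
  dln <- log(rates[i + 1]) - log(rates[i])
  dH <- -.R_KCAL * dln / dinv
  se_out <- if (is.null(se)) rep(NA_real_, length(i)) else {
    rel2 <- (se / rates)^2
    .R_KCAL * sqrt(rel2[i] + rel2[i + 1]) / abs(dinv)
  }
  structure(data.frame(T1 = temperatures[i], T2 = temperatures[i + 1],
                       T_mid = (temperatures[i] + temperatures[i + 1]) / 2,
                       dH_kcal = dH, se_kcal = se_out),
            class = c("arrhenius_fit", "data.frame"))
}

#' Ratio of two FFS rate estimates
#'
#' Refuses to compare runs performed under different thermostat schemes,
#' boxes, timesteps or diffusion scales (only relative rates at matched
#' conditions are meaningful). The CI is a bootstrap over both estimates.
#'
#' @param a,b `ffs_rate` estimates (numerator, denominator)
#' @param check_temperature require equal temperatures too (default FALSE:
#'   rate-versus-temperature series legitimately differ in T)
#' @return list with `ratio`, `se`, `ci`
#' @export
relative_rate <- function(a, b, check_temperature = FALSE) {
  stopifnot(inherits(a, "ffs_rate"), inherits(b, "ffs_rate"))
  keys <- c("kind", "scheme", "box", "diffusion_scale", "D_t", "D_r", "dt")
  if (check_temperature) keys <- c(keys, "temperature")
  for (kk in keys) {
    va <- a$conditions[[kk]]; vb <- b$conditions[[kk]]
    if (!is.null(va) && !is.null(vb) && !identical(va, vb))
      stop("comparability error: runs differ in ", kk, " (", va, " vs ",
           vb, ")")
  }
  ratio <- a$k / b$k
  rel2 <- (a$se / a$k)^2 + (b$se / b$k)^2
  nb <- min(length(a$boot), length(b$boot))
  bb <- a$boot[seq_len(nb)] / b$boot[seq_len(nb)]
  bb <- bb[is.finite(bb)]
  list(ratio = ratio, se = ratio * sqrt(rel2),
       ci = unname(quantile(bb, c(0.025, 0.975))))
}

#' Dissociation rate from the association rate and equilibrium constant
#'
#' k_off = k_on / K_eq, with first-order error propagation.
#'
#' @param k_on association rate (> 0)
#' @param K_eq equilibrium constant (> 0), same concentration convention
#' @param se_k_on,se_K_eq optional standard errors
#' @return list with `k_off` and `se`
#' @export
dissociation_rate_from_equilibrium <- function(k_on, K_eq, se_k_on = 0,
                                               se_K_eq = 0) {
  if (k_on <= 0 || K_eq <= 0)
    stop("k_on and K_eq must be positive")
  k_off <- k_on / K_eq
  rel2 <- (se_k_on / k_on)^2 + (se_K_eq / K_eq)^2
  list(k_off = k_off, se = k_off * sqrt(rel2))
}

#' First-contact position statistics
#'
#' Descriptive statistic for where along the strands initial interstrand
#' contacts form: for each state, the strand-1 position of the
#' lowest-energy detected pair, or of the closest interstrand base-site
#' pair when no pair has formed yet, scaled to [0, 1] from the 5' end
#' (0.5 = centre).
#'
#' @param states list of `dna_config` states at a contact/early interface
#' @param params a `model_parameters` object
#' @return data frame with per-state contact position (strand 1)
#' @export
first_contact_positions <- function(states, params) {
  posn <- vapply(states, function(cfg) {
    ss <- detect_base_pairs(cfg, params)
    N <- nchar(cfg$seqs[1])
    if (ss$n_total > 0) {
      i <- ss$pairs$i[which.min(ss$pairs$e)]
      return(i / (N - 1))
    }
    # closest interstrand hydrogen-bonding site pair
    hb_site <- cfg$com + params$values$pos_hb * cfg$a1
    s1 <- which(cfg$strand == 0); s2 <- which(cfg$strand == 1)
    d2 <- matrix(Inf, length(s1), length(s2))
    for (a in seq_along(s1)) {
      d <- hb_site[s2, , drop = FALSE] -
        matrix(hb_site[s1[a], ], length(s2), 3, byrow = TRUE)
      d <- d - cfg$box * round(d / cfg$box)
      d2[a, ] <- rowSums(d^2)
    }
    best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    cfg$pos[s1[best[1]]] / (N - 1)
  }, 0)
  data.frame(rel_position = posn)
}
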