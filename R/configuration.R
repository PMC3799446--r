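# Microstate container and synthetic configuration builders.
#
# A dna_config holds the full microstate: per-nucleotide rigid-body pose
# (centre of mass + right-handed orthonormal frame given by the base-face
# direction a1 and the base-stacking normal a3), velocities and angular
# momenta (unit mass, unit isotropic inertia), strand topology, a periodic
# cubic box and a temperature. All indices are 0-based.

.AVOGADRO <- 6.02214076e23

.frame_ok <- function(a1, a3, tol = 1e-6) {
  n1 <- sqrt(rowSums(a1^2)); n3 <- sqrt(rowSums(a3^2))
  dp <- rowSums(a1 * a3)
  all(abs(n1 - 1) < tol) && all(abs(n3 - 1) < tol) && all(abs(dp) < tol)
}

# native partner map (global 0-based indices, -1 where undefined):
# defined for two equal-length strands where strand 2 is the reverse
# complement of strand 1, pairing (0, i) with (1, N-1-i)
.native_map <- function(seqs) {
  n_tot <- sum(nchar(seqs))
  nat <- rep(-1L, n_tot)
  if (length(seqs) == 2 && nchar(seqs[1]) == nchar(seqs[2]) &&
      seqs[2] == reverse_complement(seqs[1])) {
    N <- nchar(seqs[1])
    i <- 0:(N - 1)
    nat[i + 1] <- N + (N - 1 - i)
    nat[N + i + 1] <- N - 1 - i
  }
  nat
}

#' Construct a configuration
#'
#' @param seqs character vector of strand sequences, 5'->3'
#' @param com,a1,a3 N x 3 matrices: centres of mass, base-face directions,
#'   base-stacking normals (frames must be orthonormal)
#' @param vel,ang N x 3 matrices of velocities and angular momenta
#'   (default zero)
#' @param box periodic cubic box edge, simulation length units
#' @param temperature temperature in kelvin
#' @return an object of class `dna_config`
#' @export
configuration <- function(seqs, com, a1, a3, vel = NULL, ang = NULL,
                          box, temperature) {
  seqs <- toupper(seqs)
  for (s in seqs) .check_bases(strsplit(s, "")[[1]])
  n_tot <- sum(nchar(seqs))
  stopifnot(nrow(com) == n_tot, nrow(a1) == n_tot, nrow(a3) == n_tot)
  if (is.null(vel)) vel <- matrix(0, n_tot, 3)
  if (is.null(ang)) ang <- matrix(0, n_tot, 3)
  if (box <= 0) stop("box edge must be > 0")
  if (!.frame_ok(a1, a3)) stop("non-orthonormal frame")
  chars <- unlist(strsplit(seqs, ""))
  structure(list(
    seqs = seqs,
    base = unname(.base_codes[chars]),
    strand = rep(seq_along(seqs) - 1L, nchar(seqs)),
    pos = unlist(lapply(nchar(seqs), function(n) 0:(n - 1))),
    nat = .native_map(seqs),
    com = unname(com), a1 = unname(a1), a3 = unname(a3),
    vel = unname(vel), ang = unname(ang),
    box = box, temperature = temperature
  ), class = "dna_config")
}

#' @export
print.dna_config <- function(x, ...) {
  cat("<dna_config>", length(x$seqs), "strand(s),", length(x$base),
      "nucleotides, box", x$box, ", T =", x$temperature, "K\n")
  for (s in x$seqs) cat("  5'-", s, "-3'\n", sep = "")
  invisible(x)
}

# argument list for the C++ kernels
.cpp_args <- function(config, params) {
  list(com = config$com, a1 = config$a1, a3 = config$a3,
       vel = config$vel, ang = config$ang,
       base = as.integer(config$base), strand = as.integer(config$strand),
       pos = as.integer(config$pos), nat = as.integer(config$nat),
       box = config$box, kT = sim_kT(config$temperature, params),
       par = params$cpp)
}

# replace pose/momentum state of a config with a C++ state list
.set_state <- function(config, state) {
  config$com <- state$com; config$a1 <- state$a1; config$a3 <- state$a3
  config$vel <- state$vel; config$ang <- state$ang
  config
}

.get_state <- function(config) {
  list(com = config$com, a1 = config$a1, a3 = config$a3,
       vel = config$vel, ang = config$ang)
}

#' Strand-pair concentration realized by a periodic box
#'
#' One strand pair per box; the molar concentration is 1 / (N_A V).
#' @param box cubic box edge in simulation length units
#' @param params a `model_parameters` object (for the length unit)
#' @export
box_concentration <- function(box, params) {
  v_l <- (box * params$units$length_nm * 1e-9)^3 * 1e3
  1 / (.AVOGADRO * v_l)
}

#' Box edge realizing a target strand-pair concentration
#' @param conc molar concentration
#' @param params a `model_parameters` object
#' @export
concentration_box <- function(conc, params) {
  v_l <- 1 / (.AVOGADRO * conc)
  (v_l / 1e3)^(1 / 3) / (params$units$length_nm * 1e-9)
}

# Maxwell-Boltzmann momenta at kT (unit mass and inertia)
.thermal_momenta <- function(n, kT) {
  list(vel = matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3),
       ang = matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3))
}

# helix placement for one nucleotide: angle phi, height z, axis ez through
# `origin`, radial frame; `sense` = +-1 gives the stacking normal direction
.helix_pose <- function(phi, z, sense, r_com, origin = c(0, 0, 0)) {
  radial <- c(cos(phi), sin(phi), 0)
  list(com = origin + r_com * radial + c(0, 0, z),
       a1 = -radial,
       a3 = c(0, 0, sense))
}

# Idealized duplex (optionally misaligned by register r) laid on a single
# helical track. Strand 1 occupies the full track; strand 2 nucleotides sit
# opposite their register-r partner position (real or extrapolated), which
# keeps both backbones smooth including unpaired tails.
.build_register_geometry <- function(seqs, r, params) {
  N <- nchar(seqs[1])
  rise <- params$helix$rise; twist <- params$helix$twist
  r_com <- params$helix$r_com
  n_tot <- 2 * N
  com <- matrix(0, n_tot, 3); a1 <- matrix(0, n_tot, 3); a3 <- matrix(0, n_tot, 3)
  for (i in 0:(N - 1)) {
    p <- .helix_pose(i * twist, i * rise, +1, r_com)
    com[i + 1, ] <- p$com; a1[i + 1, ] <- p$a1; a3[i + 1, ] <- p$a3
  }
  for (j in 0:(N - 1)) {
    i_eff <- N - 1 + r - j  # partner position on the track (may be off-range)
    p <- .helix_pose(i_eff * twist + pi, i_eff * rise, -1, r_com)
    g <- N + j
    com[g + 1, ] <- p$com; a1[g + 1, ] <- p$a1; a3[g + 1, ] <- p$a3
  }
  list(com = com, a1 = a1, a3 = a3)
}

# orthonormal frame with a1 perpendicular to a given direction
.frame_perp <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- ref - sum(ref * dir) * dir
  a1 <- a1 / sqrt(sum(a1^2))
  list(a1 = a1, a3 = dir)
}

# Two-arm pseudoknot geometry. Pair blocks are (i, N-1-i+r1) for i < split
# and (i, N-1-i+r2) for i >= split, trimmed to in-range, Watson-Crick and
# non-conflicting partners. Strand 2 threads both arms; strand 1 linkers and
# tails are interpolated/extrapolated between their anchors.
.build_pseudoknot_geometry <- function(seqs, r1, r2, split, params) {
  N <- nchar(seqs[1])
  s1 <- strsplit(seqs[1], "")[[1]]; s2 <- strsplit(seqs[2], "")[[1]]
  build_blocks <- function(ra, rb) {
    blocks <- list()
    used_j <- integer(0)
    for (blk in 1:2) {
      rr <- if (blk == 1) ra else rb
      ii <- if (blk == 1) 0:(split - 1) else split:(N - 1)
      jj <- N - 1 - ii + rr
      keep <- jj >= 0 & jj <= N - 1 & !(jj %in% used_j)
      keep[keep] <- vapply(which(keep), function(k)
        is_watson_crick(s1[ii[k] + 1], s2[jj[k] + 1]), TRUE)
      if (!any(keep)) return(NULL)
      blocks[[blk]] <- data.frame(i = ii[keep], j = jj[keep], r = rr)
      used_j <- c(used_j, jj[keep])
    }
    blocks
  }
  # the register-to-block assignment with the larger total pair count is
  # the feasible/intended one
  cand <- list(build_blocks(r1, r2), build_blocks(r2, r1))
  sizes <- vapply(cand, function(b)
    if (is.null(b)) -1L else sum(vapply(b, nrow, 0L)), 0L)
  if (max(sizes) < 2)
    stop("infeasible pseudoknot: registers (", r1, ", ", r2,
         ") admit no two-block pairing for these sequences")
  blocks <- cand[[which.max(sizes)]]
  # order arms along strand 2 (the threading strand)
  if (min(blocks[[1]]$j) > min(blocks[[2]]$j)) blocks <- blocks[c(2, 1)]
  rise <- params$helix$rise; twist <- params$helix$twist
  r_com <- params$helix$r_com
  n_tot <- 2 * N
  com <- matrix(NA_real_, n_tot, 3); a1 <- matrix(0, n_tot, 3); a3 <- matrix(0, n_tot, 3)
  # both duplex arms sit on one coaxial helical track indexed by the
  # strand-2 position, so the strand-2 path through the junction is ideal
  place_pair <- function(i, j) {
    p2 <- .helix_pose(j * twist, j * rise, +1, r_com)
    p1 <- .helix_pose(j * twist + pi, j * rise, -1, r_com)
    g2 <- N + j
    com[g2 + 1, ] <<- p2$com; a1[g2 + 1, ] <<- p2$a1; a3[g2 + 1, ] <<- p2$a3
    com[i + 1, ] <<- p1$com; a1[i + 1, ] <<- p1$a1; a3[i + 1, ] <<- p1$a3
  }
  for (b in blocks) for (k in seq_len(nrow(b))) place_pair(b$i[k], b$j[k])
  # fold the second arm back about the inter-arm junction so the strand-1
  # linker can bridge its anchors; the hinge angle is picked from a grid to
  # minimize backbone strain across both strands
  arm2_idx <- c(blocks[[2]]$i, N + blocks[[2]]$j)
  zc <- (max(blocks[[1]]$j) + min(blocks[[2]]$j)) / 2 * rise
  pivot <- c(0, 0, zc)
  strain <- function(cm) {
    pen <- 0
    for (gidx in list(0:(N - 1), N:(2 * N - 1))) {
      placed <- !is.na(cm[gidx + 1, 1])
      run <- rle(placed)
      ends <- cumsum(run$lengths)
      starts <- ends - run$lengths + 1
      for (q in seq_along(run$values)) {
        if (run$values[q]) next
        if (starts[q] == 1 || ends[q] == length(gidx)) next
        aA <- gidx[starts[q] - 1]; aB <- gidx[ends[q] + 1]
        span <- sqrt(sum((cm[aB + 1, ] - cm[aA + 1, ])^2))
        per_gap <- span / (run$lengths[q] + 1)
        pen <- pen + max(0, per_gap - 0.8)^2 * 25
      }
      # direct bonds between consecutively placed nucleotides
      for (k in seq_len(length(gidx) - 1)) {
        gA <- gidx[k]; gB <- gidx[k + 1]
        if (placed[k] && placed[k + 1]) {
          d <- sqrt(sum((cm[gB + 1, ] - cm[gA + 1, ])^2))
          pen <- pen + max(0, d - 0.95)^2 * 25
        }
      }
    }
    pen
  }
  best <- NULL; best_pen <- Inf
  for (theta in seq(0, 2.8, by = 0.2)) {
    cm <- com; aa1 <- a1; aa3 <- a3
    Rh <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
                c(-sin(theta), 0, cos(theta)))
    for (g in arm2_idx) {
      cm[g + 1, ] <- pivot + as.numeric(Rh %*% (com[g + 1, ] - pivot))
      aa1[g + 1, ] <- as.numeric(Rh %*% a1[g + 1, ])
      aa3[g + 1, ] <- as.numeric(Rh %*% a3[g + 1, ])
    }
    pen <- strain(cm)
    if (pen < best_pen) { best_pen <- pen; best <- list(cm, aa1, aa3) }
  }
  com <- best[[1]]; a1 <- best[[2]]; a3 <- best[[3]]
  # fill unplaced nucleotides: interpolate between anchors or extend tails
  fill_strand <- function(glob_idx) {
    placed <- !is.na(com[glob_idx + 1, 1])
    n <- length(glob_idx)
    k <- 1
    while (k <= n) {
      if (placed[k]) { k <- k + 1; next }
      k2 <- k
      while (k2 < n && !placed[k2 + 1]) k2 <- k2 + 1
      gap <- glob_idx[k:k2]
      prev <- if (k > 1) glob_idx[k - 1] else NA
      nxt <- if (k2 < n) glob_idx[k2 + 1] else NA
      if (!is.na(prev) && !is.na(nxt)) {
        p0 <- com[prev + 1, ]; p1v <- com[nxt + 1, ]
        m <- length(gap)
        for (t in seq_len(m)) {
          pt <- p0 + (p1v - p0) * t / (m + 1)
          fr <- .frame_perp(p1v - p0)
          com[gap[t] + 1, ] <<- pt
          a1[gap[t] + 1, ] <<- fr$a1; a3[gap[t] + 1, ] <<- fr$a3
        }
      } else {
        anchor <- if (!is.na(prev)) prev else nxt
        dir <- a3[anchor + 1, ]
        if (is.na(prev)) dir <- -dir
        step <- 0.64
        for (t in seq_along(gap)) {
          g <- gap[if (!is.na(prev)) t else length(gap) - t + 1]
          com[g + 1, ] <<- com[anchor + 1, ] + dir * step * t
          fr <- .frame_perp(dir)
          a1[g + 1, ] <<- fr$a1; a3[g + 1, ] <<- fr$a3
        }
      }
      k <- k2 + 1
    }
  }
  fill_strand(0:(N - 1))
  fill_strand(N:(2 * N - 1))
  list(com = com, a1 = a1, a3 = a3,
       registers = c(blocks[[1]]$r[1], blocks[[2]]$r[1]))
}

# random 3D rotation matrix (uniform via QR of gaussian matrix)
.random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Build an initial configuration
#'
#' Generates the structured starting states used by the hybridization study:
#' `separated_strands` (two pre-oriented single strands placed with an
#' interstrand separation above the unbound-basin cutoff), `native_duplex`
#' (all native pairs formed on an idealized helix), `misaligned` (the
#' maximal base-pair set of a given register `r`), and `pseudoknot` (two
#' duplex blocks in registers `r1`, `r2` split at strand position `split`,
#' giving a non-monotonic partner mapping). Momenta are drawn from the
#' Maxwell-Boltzmann distribution at `temperature`; `relax_sweeps` optional
#' Monte Carlo sweeps settle the idealized geometry.
#'
#' @param sequences two-strand character vector (5'->3') or a preset name
#' @param mode one of `"separated_strands"`, `"native_duplex"`,
#'   `"misaligned"`, `"pseudoknot"`
#' @param box cubic box edge (simulation length units); alternatively give
#'   `concentration` (molar) and the box is derived
#' @param temperature kelvin
#' @param params a `model_parameters` object
#' @param register register r for `misaligned`
#' @param registers length-2 integer vector (r1, r2) for `pseudoknot`
#' @param split strand-1 position separating the two pseudoknot blocks
#' @param min_separation required interstrand distance for
#'   `separated_strands` (defaults to the unbound-basin cutoff 1.5)
#' @param relax_sweeps Monte Carlo sweeps of relaxation after construction
#' @param seed RNG seed (mandatory for reproducible stochastic placement)
#' @return a `dna_config`
#' @export
build_configuration <- function(sequences, mode = c("separated_strands",
                                                    "native_duplex",
                                                    "misaligned", "pseudoknot"),
                                box = NULL, temperature = 300,
                                params = load_parameters("average"),
                                register = NULL, registers = NULL, split = NULL,
                                concentration = NULL,
                                min_separation = 1.5, relax_sweeps = 0,
                                seed = 1) {
  mode <- match.arg(mode)
  if (is.character(sequences) && length(sequences) == 1)
    sequences <- sequence_presets(sequences)
  seqs <- toupper(as.character(sequences))
  if (length(seqs) != 2) stop("build_configuration expects two strands")
  N <- nchar(seqs[1])
  if (is.null(box)) {
    if (is.null(concentration)) stop("give either box or concentration")
    box <- concentration_box(concentration, params)
  }
  set.seed(seed)
  kT <- sim_kT(temperature, params)

  if (mode == "native_duplex" || mode == "misaligned") {
    r <- if (mode == "native_duplex") 0L else as.integer(register)
    if (mode == "misaligned") {
      if (is.null(register)) stop("misaligned mode needs a register")
      if (max_pairs_in_register(seqs[1], seqs[2], r) == 0)
        stop("infeasible register ", r, " for these sequences: ",
             "no Watson-Crick pairs at that offset")
    }
    geo <- .build_register_geometry(seqs, r, params)
  } else if (mode == "pseudoknot") {
    if (is.null(registers) || length(registers) != 2)
      stop("pseudoknot mode needs registers = c(r1, r2)")
    if (is.null(split)) split <- N %/% 2
    geo <- .build_pseudoknot_geometry(seqs, registers[1], registers[2],
                                      split, params)
  } else { # separated_strands
    geo1 <- .build_register_geometry(seqs, 0L, params)
    com <- geo1$com; a1 <- geo1$a1; a3 <- geo1$a3
    idx1 <- 1:N; idx2 <- (N + 1):(2 * N)
    for (idx in list(idx1, idx2)) {
      R <- .random_rotation()
      ctr <- colMeans(com[idx, , drop = FALSE])
      com[idx, ] <- t(R %*% (t(com[idx, , drop = FALSE]) - ctr))
      a1[idx, ] <- t(R %*% t(a1[idx, , drop = FALSE]))
      a3[idx, ] <- t(R %*% t(a3[idx, , drop = FALSE]))
    }
    sep <- box / 2
    com[idx1, 1] <- com[idx1, 1] - sep / 2
    com[idx2, 1] <- com[idx2, 1] + sep / 2
    geo <- list(com = com, a1 = a1, a3 = a3)
  }

  mom <- .thermal_momenta(2 * N, kT)
  cfg <- configuration(seqs, geo$com, geo$a1, geo$a3, mom$vel, mom$ang,
                       box = box, temperature = temperature)

  if (mode == "separated_strands") {
    dmin <- do.call(cpp_min_interstrand_dist, .cpp_args(cfg, params))
    if (dmin <= min_separation)
      stop("infeasible separated_strands placement: interstrand distance ",
           signif(dmin, 3), " <= required ", min_separation,
           " (box too small for these strands)")
  }
  if (relax_sweeps > 0)
    cfg <- vmmc_sweep(cfg, params, n_sweeps = relax_sweeps)
  cfg
}
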