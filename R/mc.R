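# Equilibrium sampling: cluster-move Monte Carlo and umbrella sampling.

#' Cluster-move Monte Carlo sweeps
#'
#' Runs Metropolis Monte Carlo at the configuration's temperature using
#' single-nucleotide translations/rotations mixed with rigid moves of
#' energetically connected clusters, so bound duplexes diffuse without
#' artificial suppression. A cluster move that would change the cluster's
#' membership is rejected, keeping the proposal symmetric; the chain then
#' satisfies detailed balance with respect to the Boltzmann distribution
#' (times the umbrella weight when `bias` is given).
#'
#' @param config a `dna_config`
#' @param params a `model_parameters` object
#' @param n_sweeps number of sweeps (N move attempts each)
#' @param bias optional `bias_spec` umbrella weights
#' @param sigma_tr,sigma_rot single-move displacement / rotation scales
#' @param p_cluster probability that an attempt is a cluster move
#' @param bond_energy pair-energy threshold defining cluster connectivity
#' @param store_stride store a frame every this many sweeps (0: none)
#' @param log_moves keep a per-move log (dE, weight ratio, accepted) for
#'   detailed-balance audits
#' @param seed optional RNG seed
#' @return the updated `dna_config`; attributes `mc` (acceptance rates,
#'   base-pair histogram, stored frames and their base-pair counts) and,
#'   if requested, `move_log`
#' @export
vmmc_sweep <- function(config, params, n_sweeps = 1, bias = NULL,
                       sigma_tr = 0.12, sigma_rot = 0.22, p_cluster = 0.2,
                       bond_energy = -0.1, store_stride = 0,
                       log_moves = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- if (is.null(bias)) numeric(0) else bias$weights
  count_native <- if (is.null(bias)) FALSE else identical(bias$op, "n_native")
  res <- do.call(cpp_mc_run, c(
    .cpp_args(config, params),
    list(nsweeps = as.integer(n_sweeps), sigma_tr = sigma_tr,
         sigma_rot = sigma_rot, p_cluster = p_cluster, bond_e = bond_energy,
         bias = as.numeric(w), thr = pairing_threshold(params),
         native_count = count_native, store_stride = as.integer(store_stride),
         log_moves = log_moves, max_log = 200000L)))
  out <- .set_state(config, res$state)
  attr(out, "mc") <- list(hist = res$hist, n_final = res$n_final,
                          acc_single = res$acc_single,
                          acc_cluster = res$acc_cluster,
                          frames = res$frames, frame_n = res$frame_n)
  if (log_moves) attr(out, "move_log") <- res$move_log
  out
}

#' Umbrella bias specification
#'
#' Positive weights over an order parameter (the number of native or total
#' base pairs n). Sampling is biased by w(n) and the recorded histogram is
#' reweighted by 1/w(n).
#'
#' @param weights positive numeric vector, element k is the weight of
#'   n = k - 1
#' @param op `"n_native"` or `"n_total"`
#' @export
bias_spec <- function(weights, op = c("n_native", "n_total")) {
  op <- match.arg(op)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("umbrella weights must be positive")
  structure(list(weights = weights, op = op), class = "bias_spec")
}

#' Reweight a biased histogram
#'
#' Exact unbiasing identity: P(n) proportional to counts(n) / w(n).
#' @param counts visit counts per order-parameter value (0-based support)
#' @param weights umbrella weights aligned with `counts` (recycled if
#'   shorter; uniform weights recover the plain estimate)
#' @return normalized probabilities over the sampled support
#' @export
reweight_histogram <- function(counts, weights = 1) {
  w <- rep_len(weights, length(counts))
  p <- counts / w
  s <- sum(p)
  if (s <= 0) stop("empty histogram: nothing to reweight")
  p / s
}

#' Umbrella-sampled free-energy profile over base-pair number
#'
#' Runs biased cluster-move Monte Carlo, reweights the visit histogram by
#' 1/w(n), and returns the free-energy profile F(n) = -kT ln P(n), offset
#' so the sampled minimum is zero. Uncertainties are estimated by block
#' averaging over `n_blocks` sequential segments. Values of n never visited
#' are marked unsampled (NA) rather than invented.
#'
#' @param config a `dna_config` (typically a duplex)
#' @param params a `model_parameters` object
#' @param bias a `bias_spec`; the bias should cover the reachable n range
#' @param sweeps total Monte Carlo sweeps
#' @param n_blocks blocks for the block-averaged uncertainty
#' @param burn_in sweeps discarded before accumulation
#' @param seed optional RNG seed
#' @param ... further arguments passed to [vmmc_sweep()]
#' @return a `free_energy_profile`: data frame with n, P, F_kT, F_kcal,
#'   se_kT, sampled; attribute `temperature`
#' @export
run_umbrella <- function(config, params, bias, sweeps, n_blocks = 10,
                         burn_in = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (burn_in > 0)
    config <- vmmc_sweep(config, params, n_sweeps = burn_in, bias = bias, ...)
  block_sweeps <- max(1, floor(sweeps / n_blocks))
  hists <- matrix(0, n_blocks, 0)
  hlist <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    config <- vmmc_sweep(config, params, n_sweeps = block_sweeps,
                         bias = bias, ...)
    hlist[[b]] <- attr(config, "mc")$hist
  }
  nbin <- max(lengths(hlist))
  H <- t(vapply(hlist, function(h) { length(h) <- nbin; h[is.na(h)] <- 0; h },
                numeric(nbin)))
  counts <- colSums(H)
  n_vals <- 0:(nbin - 1)
  w <- rep_len(bias$weights, nbin)
  sampled <- counts > 0
  P <- rep(NA_real_, nbin)
  P[sampled] <- reweight_histogram(counts[sampled], w[sampled])
  # block-level profiles for the uncertainty
  FkT_blocks <- matrix(NA_real_, n_blocks, nbin)
  for (b in seq_len(n_blocks)) {
    ok <- H[b, ] > 0
    if (sum(ok) > 0) {
      pb <- reweight_histogram(H[b, ok], w[ok])
      FkT_blocks[b, ok] <- -log(pb)
      FkT_blocks[b, ok] <- FkT_blocks[b, ok] - min(FkT_blocks[b, ok], na.rm = TRUE)
    }
  }
  kT <- sim_kT(config$temperature, params)
  FkT <- -log(P)
  FkT <- FkT - min(FkT, na.rm = TRUE)
  se <- apply(FkT_blocks, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(NA_real_)
    sd(col) / sqrt(length(col))
  })
  prof <- data.frame(n = n_vals, P = P, F_kT = FkT,
                     F_kcal = FkT * kT * params$units$energy_kcal_mol,
                     se_kT = se, sampled = sampled)
  structure(prof, class = c("free_energy_profile", "data.frame"),
            temperature = config$temperature)
}

#' Iteratively adapt umbrella weights toward a flat histogram
#'
#' Each round runs biased sweeps and accumulates a reweighted estimate of
#' the unbiased distribution P(n) over all rounds; the next weights are
#' proportional to 1/P(n) (normalized), so the visit histogram flattens as
#' the estimate converges. Unsampled n values inherit the smallest observed
#' probability, the log-weight jump between adjacent n is capped to keep
#' the chain connected, and with `exclude_unbound` (the default) the
#' unbound state n = 0 carries a vanishing weight so the profile stays in
#' the bound, concentration-independent manifold. The weights are frozen
#' after `n_iter` rounds for production use.
#'
#' @param config a `dna_config`
#' @param params a `model_parameters` object
#' @param n_max largest base-pair count to cover
#' @param n_iter adaptation rounds
#' @param sweeps_per_iter sweeps per round
#' @param op order parameter, as in [bias_spec()]
#' @param exclude_unbound suppress visits to n = 0
#' @param log_cap largest |log-weight| difference between adjacent n
#' @param seed optional RNG seed
#' @param ... passed to [vmmc_sweep()]
#' @return a `bias_spec` with the adapted weights
#' @export
adapt_umbrella_weights <- function(config, params, n_max, n_iter = 8,
                                   sweeps_per_iter = 1000, op = "n_native",
                                   exclude_unbound = TRUE, log_cap = 6,
                                   seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nb <- n_max + 1
  w <- rep(1, nb)
  acc <- rep(0, nb)       # accumulated unbiased visit estimate
  clamp <- function(w) {
    lw <- log(w)
    for (k in 2:nb) lw[k] <- min(max(lw[k], lw[k - 1] - log_cap),
                                 lw[k - 1] + log_cap)
    w <- exp(lw - max(lw))
    if (exclude_unbound) w[1] <- min(w[-1]) * 1e-9
    w
  }
  w <- clamp(w)
  for (it in seq_len(n_iter)) {
    b <- bias_spec(w, op = op)
    config <- vmmc_sweep(config, params, n_sweeps = sweeps_per_iter,
                         bias = b, ...)
    h <- attr(config, "mc")$hist
    length(h) <- nb
    h[is.na(h)] <- 0
    acc <- acc + h / w
    # exploration phase: push the chain into unvisited n aggressively
    w <- clamp(w / pmax(h, 1))
  }
  # consolidate: final weights from the accumulated unbiased estimate
  p <- acc
  if (exclude_unbound) p[1] <- 0
  pos <- p > 0
  if (any(pos)) {
    p[!pos] <- min(p[pos])
    w <- clamp(1 / p)
  }
  bias_spec(w, op = op)
}
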