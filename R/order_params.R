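# Secondary-structure descriptors: base pairs, registers, pseudoknots, and
# the staged order parameter used by forward flux sampling.
#
# Register convention: with both strands indexed 0..N-1 from their 5' ends
# and the native partner of strand-1 position i being strand-2 position
# N-1-i, a pair (i, j) has register r = j - (N - 1 - i). r = 0 is correct
# alignment. A partner mapping that is non-monotonic in j along increasing
# i is a pseudoknot, described by its two dominant registers (r1, r2).

#' Construct a secondary structure from an explicit pair list
#'
#' Used both by [detect_base_pairs()] and to build synthetic structure
#' sequences for pathway classification.
#'
#' @param pairs data frame with columns `i` (strand-1 position), `j`
#'   (strand-2 position), optionally `e` (hydrogen-bond energy); 0-based
#' @param n strand length N
#' @return an object of class `secondary_structure`
#' @export
secondary_structure <- function(pairs, n) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(i = integer(0), j = integer(0), e = numeric(0),
                        native = logical(0), register = integer(0))
  } else {
    if (!"e" %in% names(pairs)) pairs$e <- NA_real_
    if (anyDuplicated(pairs$i) || anyDuplicated(pairs$j))
      stop("each base may appear in at most one pair")
    pairs$register <- pairs$j - (n - 1 - pairs$i)
    pairs$native <- pairs$register == 0L
    pairs <- pairs[order(pairs$i), ]
  }
  reg_hist <- table(pairs$register)
  pk <- .pseudoknot_descriptor(pairs)
  structure(list(pairs = pairs, n = n,
                 n_total = nrow(pairs),
                 n_native = sum(pairs$native),
                 register_hist = reg_hist,
                 pseudoknot = pk), class = "secondary_structure")
}

# non-monotonic partner mapping => pseudoknot; descriptor = the two dominant
# registers, sorted decreasing
.pseudoknot_descriptor <- function(pairs) {
  if (nrow(pairs) < 2) return(NULL)
  j <- pairs$j[order(pairs$i)]
  if (all(diff(j) < 0) || all(diff(j) > 0)) return(NULL)
  regs <- pairs$register
  cnt <- sort(table(regs), decreasing = TRUE)
  r2 <- as.integer(names(cnt))[1:2]
  sort(r2, decreasing = TRUE)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure>", x$n_total, "pairs (", x$n_native, "native )\n")
  if (x$n_total > 0) {
    cat("  registers:", paste(names(x$register_hist), x$register_hist,
                              sep = ":", collapse = " "), "\n")
  }
  if (!is.null(x$pseudoknot))
    cat("  pseudoknot (", x$pseudoknot[1], ",", x$pseudoknot[2], ")\n")
  invisible(x)
}

# dominant register; ties broken by the register with the lowest-energy
# pair block
.dominant_register <- function(struct) {
  if (struct$n_total == 0) return(NA_integer_)
  h <- struct$register_hist
  top <- as.integer(names(h)[h == max(h)])
  if (length(top) == 1) return(top)
  esum <- vapply(top, function(r)
    sum(struct$pairs$e[struct$pairs$register == r], na.rm = TRUE), 0)
  top[which.min(esum)]
}

#' Detect base pairs and classify the secondary structure
#'
#' A base pair is an interstrand (i, j) whose hydrogen-bond term is at or
#' below `threshold`; when a base satisfies the threshold with two partners
#' the lower-energy pair is kept (ties resolved toward the lower partner
#' index). Registers, the register histogram and the pseudoknot descriptor
#' follow from the partner mapping. Detection is deterministic.
#'
#' @param config a `dna_config` with two strands
#' @param params a `model_parameters` object
#' @param threshold pairing energy threshold (< 0); defaults to
#'   [pairing_threshold()]
#' @return a `secondary_structure`
#' @export
detect_base_pairs <- function(config, params, threshold = NULL) {
  if (is.null(threshold)) threshold <- pairing_threshold(params)
  if (threshold >= 0) stop("pairing threshold must be negative")
  m <- do.call(cpp_base_pairs, c(.cpp_args(config, params),
                                 list(thr = threshold,
                                      native_only_count = FALSE)))
  N <- nchar(config$seqs[1])
  if (nrow(m) == 0) return(secondary_structure(NULL, N))
  g1 <- pmin(m[, 1], m[, 2]); g2 <- pmax(m[, 1], m[, 2])
  inter <- config$strand[g1 + 1] == 0 & config$strand[g2 + 1] == 1
  m <- m[inter, , drop = FALSE]
  if (nrow(m) == 0) return(secondary_structure(NULL, N))
  pairs <- data.frame(i = config$pos[pmin(m[, 1], m[, 2]) + 1],
                      j = config$pos[pmax(m[, 1], m[, 2]) + 1],
                      e = m[, 3])
  secondary_structure(pairs, N)
}

#' Maximum base pairs available in a register
#'
#' Counts the positions at which juxtaposing the strands with offset `r`
#' gives Watson-Crick complementary bases; this bounds the size of a purely
#' misaligned structure of that register. For all r the count is at most
#' N - |r|.
#'
#' @param seq1,seq2 strand sequences, 5'->3'
#' @param r integer register, |r| < N
#' @export
max_pairs_in_register <- function(seq1, seq2, r) {
  s1 <- strsplit(toupper(seq1), "")[[1]]
  s2 <- strsplit(toupper(seq2), "")[[1]]
  N <- length(s1)
  stopifnot(length(s2) == N, abs(r) < N)
  cnt <- 0L
  for (i in 0:(N - 1)) {
    j <- N - 1 - i + r
    if (j >= 0 && j <= N - 1 && is_watson_crick(s1[i + 1], s2[j + 1]))
      cnt <- cnt + 1L
  }
  cnt
}

#' Staged order-parameter definition
#'
#' The reaction coordinate used for forward flux sampling: lambda = 0 in the
#' unbound basin (minimum interstrand site distance above `d_basin`),
#' lambda = 1 on interstrand contact (distance at or below `d_contact`),
#' and lambda = 1 + n when n base pairs are formed; intermediate separations
#' score 0.5. The scale is totally ordered and monotone in progress toward
#' the duplex by construction.
#'
#' @param n_target base pairs defining the full duplex
#' @param params a `model_parameters` object (for the pairing threshold)
#' @param d_contact contact distance (simulation length units)
#' @param d_basin unbound-basin distance (> d_contact)
#' @param count `"native"` or `"total"` base pairs for the staged values
#' @param threshold pairing threshold override
#' @export
order_parameter_spec <- function(n_target, params, d_contact = 0.8,
                                 d_basin = 1.5,
                                 count = c("native", "total"),
                                 threshold = NULL) {
  count <- match.arg(count)
  stopifnot(d_basin > d_contact)
  if (is.null(threshold)) threshold <- pairing_threshold(params)
  structure(list(thr = threshold, d_contact = d_contact, d_basin = d_basin,
                 native_count = count == "native",
                 n_target = as.integer(n_target),
                 lambda_target = 1 + as.integer(n_target)),
            class = "op_spec")
}

#' Evaluate the staged order parameter
#' @param config a `dna_config`
#' @param spec an `op_spec` from [order_parameter_spec()]
#' @param params a `model_parameters` object
#' @return scalar lambda on the staged ordered scale
#' @export
eval_order_parameter <- function(config, spec, params) {
  if (!inherits(spec, "op_spec")) stop("unknown order-parameter spec")
  do.call(cpp_lambda, c(.cpp_args(config, params),
                        list(opspec = unclass(spec))))
}

#' Serialize secondary structures to a per-frame tabular log
#' @param structures list of `secondary_structure`
#' @return data frame: frame, n_total, n_native, registers (r:count),
#'   pseudoknot
#' @export
structure_log <- function(structures) {
  data.frame(
    frame = seq_along(structures) - 1L,
    n_total = vapply(structures, function(s) s$n_total, 0L),
    n_native = vapply(structures, function(s) s$n_native, 0L),
    registers = vapply(structures, function(s)
      paste(names(s$register_hist), s$register_hist, sep = ":",
            collapse = " "), ""),
    pseudoknot = vapply(structures, function(s)
      if (is.null(s$pseudoknot)) "" else
        paste(s$pseudoknot, collapse = ","), "")
  )
}
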