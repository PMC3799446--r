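# Plain-text readers/writers for topology, configuration and results
# bundles.
#
# Dialect (documented once, enforced by the readers): the topology file
# starts with "<n_nucleotides> <n_strands>", followed by one row per
# nucleotide, global order = strands concatenated 5'->3', each row
# "<strand> <base> <prev> <next>" with 0-based strand indices and global
# indices of the 5' and 3' bonded neighbours (-1 at strand ends). The
# configuration file has a three-line header
#   t = <time>
#   b = <L> <L> <L>
#   E = <total> <potential> <kinetic>
# followed by one row per nucleotide: position (3), base-face direction a1
# (3), stacking normal a3 (3), velocity (3), angular momentum (3), printed
# at full precision so that write -> read round-trips bit-exactly.

.fmt <- function(x) sprintf("%.17g", x)

#' Write topology and configuration files
#'
#' @param config a `dna_config`
#' @param topology,configuration output paths
#' @param time time stamp for the configuration header
#' @param params optional `model_parameters` for the energy header
#'   (zeros are written when omitted)
#' @export
write_topology_configuration <- function(config, topology, configuration,
                                         time = 0, params = NULL) {
  n <- length(config$base)
  prev_i <- integer(n); next_i <- integer(n)
  for (g in seq_len(n) - 1L) {
    s <- config$strand[g + 1]; p <- config$pos[g + 1]
    prev_i[g + 1] <- if (p == 0) -1L else g - 1L
    last <- sum(config$strand <= s) - 1L
    next_i[g + 1] <- if (g == last) -1L else g + 1L
  }
  top <- c(paste(n, length(config$seqs)),
           paste(config$strand, .bases[config$base + 1], prev_i, next_i))
  writeLines(top, topology)

  epot <- 0; ekin <- 0
  if (!is.null(params)) {
    epot <- total_energy(config, params)$energy$total
    ekin <- 0.5 * sum(config$vel^2) + 0.5 * sum(config$ang^2)
  }
  rows <- apply(cbind(config$com, config$a1, config$a3,
                      config$vel, config$ang), 1,
                function(r) paste(.fmt(r), collapse = " "))
  hdr <- c(paste("t =", .fmt(time)),
           paste("b =", .fmt(config$box), .fmt(config$box), .fmt(config$box)),
           paste("E =", .fmt(epot + ekin), .fmt(epot), .fmt(ekin)))
  writeLines(c(hdr, rows), configuration)
  invisible(c(topology = topology, configuration = configuration))
}

#' Write a trajectory as concatenated configuration blocks
#'
#' Each frame of an [evolve()] trajectory is written as one configuration
#' block (header + per-nucleotide rows) in the same dialect as
#' [write_topology_configuration()]; frames round-trip bit-exactly through
#' [read_trajectory()].
#'
#' @param trajectory result of [evolve()] with `store_frames = TRUE`, or a
#'   list of state lists
#' @param config the `dna_config` the frames belong to (topology and box)
#' @param path output path for the trajectory file
#' @param times optional frame time stamps
#' @export
write_trajectory <- function(trajectory, config, path, times = NULL) {
  frames <- if (!is.null(trajectory$frames)) trajectory$frames else trajectory
  if (length(frames) == 0) stop("no frames to write")
  if (is.null(times)) times <- seq_along(frames) - 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    ekin <- 0.5 * sum(f$vel^2) + 0.5 * sum(f$ang^2)
    writeLines(c(paste("t =", .fmt(times[k])),
                 paste("b =", .fmt(config$box), .fmt(config$box),
                       .fmt(config$box)),
                 paste("E =", .fmt(ekin), .fmt(0), .fmt(ekin))), con)
    rows <- apply(cbind(f$com, f$a1, f$a3, f$vel, f$ang), 1,
                  function(r) paste(.fmt(r), collapse = " "))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path trajectory file
#' @param config the `dna_config` providing the topology
#' @return list of `dna_config` frames
#' @export
read_trajectory <- function(path, config) {
  lines <- readLines(path)
  n <- length(config$base)
  block <- n + 3
  if (length(lines) %% block != 0)
    .parse_err(path, length(lines),
               paste0("length is not a multiple of the frame size ", block))
  nframes <- length(lines) %/% block
  lapply(seq_len(nframes), function(k) {
    off <- (k - 1) * block
    M <- t(vapply(seq_len(n), function(r)
      as.numeric(strsplit(trimws(lines[off + 3 + r]), "\\s+")[[1]]),
      numeric(15)))
    cfg <- config
    cfg$com <- M[, 1:3]; cfg$a1 <- M[, 4:6]; cfg$a3 <- M[, 7:9]
    cfg$vel <- M[, 10:12]; cfg$ang <- M[, 13:15]
    cfg
  })
}

.parse_err <- function(file, line, msg) {
  stop("parse error in ", file, " at line ", line, ": ", msg, call. = FALSE)
}

#' Read topology and configuration files
#'
#' Parses the plain-text dialect written by
#' [write_topology_configuration()], validating the nucleotide count,
#' strand connectivity and frame orthonormality.
#'
#' @param topology,configuration input paths
#' @param temperature temperature (kelvin) to attach to the state (the
#'   files do not carry one)
#' @return a `dna_config`
#' @export
read_topology_configuration <- function(topology, configuration,
                                        temperature = 300) {
  if (!file.exists(topology)) stop("no such topology file: ", topology)
  if (!file.exists(configuration))
    stop("no such configuration file: ", configuration)
  tl <- readLines(topology)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(tl[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr))
    .parse_err(topology, 1, "expected '<n_nucleotides> <n_strands>'")
  n <- hdr[1]; ns <- hdr[2]
  if (length(tl) - 1 != n)
    .parse_err(topology, length(tl),
               paste0("topology declares ", n, " nucleotides but has ",
                      length(tl) - 1, " rows"))
  strand <- integer(n); basech <- character(n)
  prev_i <- integer(n); next_i <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(tl[k + 1]), "\\s+")[[1]]
    if (length(f) != 4)
      .parse_err(topology, k + 1, "expected 4 fields (strand base prev next)")
    strand[k] <- as.integer(f[1]); basech[k] <- f[2]
    prev_i[k] <- as.integer(f[3]); next_i[k] <- as.integer(f[4])
    if (!basech[k] %in% .bases)
      .parse_err(topology, k + 1, paste0("invalid base '", f[2], "'"))
  }
  if (length(unique(strand)) != ns)
    .parse_err(topology, 1, "strand count does not match declared strands")
  # bonded neighbours must be intra-strand and adjacent in 5'->3' order
  for (k in seq_len(n)) {
    for (nb in c(prev_i[k], next_i[k])) {
      if (nb >= 0 && (nb >= n || strand[nb + 1] != strand[k] ||
                      abs(nb - (k - 1)) != 1))
        .parse_err(topology, k + 1, "inconsistent bonded-neighbour indices")
    }
  }
  seqs <- vapply(split(basech, strand), paste, "", collapse = "")

  cl <- readLines(configuration)
  if (length(cl) != n + 3)
    .parse_err(configuration, length(cl),
               paste0("expected ", n + 3, " lines (3 header + ", n,
                      " nucleotide rows), found ", length(cl)))
  bx <- strsplit(trimws(cl[2]), "\\s+")[[1]]
  if (length(bx) != 5 || bx[1] != "b")
    .parse_err(configuration, 2, "expected 'b = L L L'")
  box <- as.numeric(bx[3])
  M <- matrix(NA_real_, n, 15)
  for (k in seq_len(n)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(cl[k + 3]), "\\s+")[[1]]))
    if (length(f) != 15 || anyNA(f))
      .parse_err(configuration, k + 3,
                 "expected 15 numeric fields (pos a1 a3 vel ang)")
    M[k, ] <- f
  }
  configuration(unname(seqs), com = M[, 1:3], a1 = M[, 4:6], a3 = M[, 7:9],
                vel = M[, 10:12], ang = M[, 13:15], box = box,
                temperature = temperature)
}

#' Write a structured results bundle
#'
#' A bundle couples the exact run configuration and seeds with the result
#' tables so that any results directory is reproducible from its own
#' content. Tables are written as TSV, the config snapshot and summary as
#' JSON. Writing is deterministic: equal bundles give byte-identical files.
#'
#' @param bundle list with required fields `config` (run configuration,
#'   serialized verbatim), `seeds` (named or plain vector), `tables`
#'   (named list of data frames) and `summary` (named list of scalars)
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_results <- function(bundle, dir) {
  required <- c("config", "seeds", "tables", "summary")
  missing <- setdiff(required, names(bundle))
  if (length(missing) > 0)
    stop("refusing to finalize incomplete results bundle; missing: ",
         paste(missing, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "run_config.json")
  jsonlite::write_json(bundle$config, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "seeds.json")
  jsonlite::write_json(as.list(bundle$seeds), p, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, p)
  for (nm in names(bundle$tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(bundle$tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(bundle$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
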