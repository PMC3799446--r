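# Bases, Watson-Crick complementarity, study sequence presets, FASTA input.

.base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.check_bases <- function(x) {
  bad <- setdiff(unique(x), .bases)
  if (length(bad) > 0)
    stop("invalid base identity: ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Complement of a base or sequence
#'
#' The complement map is the involution A<->T, C<->G.
#' @param x character vector of single bases, or a sequence string
#' @export
complement_base <- function(x) {
  .check_bases(x)
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

#' Reverse complement of a 5'->3' sequence string
#' @param seq sequence string, 5'->3'
#' @return the complementary strand, also written 5'->3'
#' @export
reverse_complement <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  paste(rev(complement_base(b)), collapse = "")
}

#' Watson-Crick complementarity test
#'
#' TRUE iff \{a, b\} is \{A, T\} or \{C, G\}; symmetric in its arguments.
#' Hydrogen bonding in the model is nonzero only for such pairs.
#' @param a,b single base identities
#' @export
is_watson_crick <- function(a, b) {
  .check_bases(c(a, b))
  (.base_codes[[a]] + .base_codes[[b]]) == 3L
}

#' Study sequence presets
#'
#' The strand pairs used throughout the hybridization study: a 14-mer pair
#' designed to limit non-intended base pairing (`nonrepetitive14`), a
#' maximally repetitive AC/GT 14-mer pair that supports many misaligned
#' registers (`repeat14`), and three 8-mer duplexes of differing G-C content
#' (`gc8`, `avg8`, `at8`) used for sequence-dependent binding rates.
#' All sequences are written 5'->3'; the second strand is the reverse
#' complement of the first.
#'
#' @param name optional preset name; when omitted all presets are returned.
#' @return a named list of length-2 character vectors (the two strands),
#'   each carrying a `provenance` attribute.
#' @export
sequence_presets <- function(name = NULL) {
  mk <- function(s1, label) {
    structure(c(s1, reverse_complement(s1)), provenance = label)
  }
  presets <- list(
    nonrepetitive14 = mk("TATCTGGCTTGTCG", "14-mer designed against misbonding"),
    repeat14 = mk("ACACACACACACAC", "maximally repetitive AC/GT 14-mer"),
    gc8 = mk("CCCGCCGC", "G-C-rich 8-mer"),
    avg8 = mk("TCTCCATG", "average-strength 8-mer"),
    at8 = mk("ATTTATTA", "A-T-rich 8-mer")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown sequence preset: ", name)
  presets[[name]]
}

#' Read strand sequences from FASTA or inline strings
#'
#' @param x a path to a FASTA file, or a character vector of sequences
#'   (5'->3').
#' @return character vector of upper-case sequences
#' @export
read_sequences <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    lines <- readLines(x)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("not a FASTA file (no '>' headers): ", x)
    idx <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                   function(s) paste(trimws(s), collapse = ""), "")
    names(seqs) <- sub("^>\\s*", "", lines[hdr])
    x <- seqs
  }
  x <- toupper(gsub("\\s", "", x))
  for (s in x) .check_bases(strsplit(s, "")[[1]])
  x
}
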