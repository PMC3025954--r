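#' Seed dif sequence
#'
#' A 28-bp experimentally confirmed or previously predicted dif site used to
#' bootstrap a clade's first profile.
#'
#' @param organism organism the seed comes from.
#' @param sequence 28-base string over \code{A,C,G,T}.
#' @param provenance \code{"experimental"} or \code{"computational"}.
#' @return object of class \code{seed_dif}.
#' @export
seed_dif <- function(organism, sequence,
                     provenance = c("experimental", "computational")) {
  provenance <- match.arg(provenance)
  sequence <- toupper(sequence)
  if (nchar(sequence) != 28L)
    stopf("seed dif must be exactly 28 bases (got %d)", nchar(sequence))
  if (grepl("[^ACGT]", sequence))
    stopf("seed dif must be over {A,C,G,T}")
  structure(list(organism = organism, sequence = sequence,
                 provenance = provenance), class = "seed_dif")
}

#' Published seed dif sites
#'
#' The three seeds used to bootstrap the Proteobacteria, Firmicutes and
#' Actinobacteria searches: Escherichia coli K-12 and Bacillus subtilis 168
#' (experimental) and Frankia alni ACN14a (computational).
#'
#' @return named list of \code{\link{seed_dif}} objects
#'   (\code{e_coli}, \code{b_subtilis}, \code{f_alni}).
#' @export
published_seeds <- function() {
  list(
    e_coli = seed_dif("Escherichia coli K-12",
                      "GGTGCGCATAATGTATATTATGTTAAAT", "experimental"),
    b_subtilis = seed_dif("Bacillus subtilis 168",
                          "ACTTCCTAGAATATATATTATGTAAACT", "experimental"),
    f_alni = seed_dif("Frankia alni ACN14a",
                      "CACGCCGATAATGCACATTATGTCAAGT", "computational"))
}

#' Fuzzy (substitution-only) scan for a seed dif
#'
#' Every 28-base window on both strands of the circular chromosome —
#' including windows wrapping the sequence origin — whose Hamming distance to
#' the seed is at most \code{max_substitutions} is returned. Insertions and
#' deletions are never considered; windows containing \code{N} are skipped.
#'
#' @param chromosome a circular \code{\link{chromosome}}.
#' @param seed a \code{\link{seed_dif}} (or bare 28-mer string).
#' @param max_substitutions maximum Hamming distance, 0-28 (default 8).
#' @return data frame of class \code{fuzzy_hits} with columns
#'   \code{chromosome}, \code{start} (1-based, leftmost forward-strand
#'   position of the window), \code{strand}, \code{substitutions},
#'   \code{matched} (window as read 5'-3' on the hit strand), sorted by
#'   substitutions then start then strand.
#' @export
fuzzy_scan <- function(chromosome, seed, max_substitutions = 8) {
  if (chromosome$topology != "circular")
    stopf("fuzzy_scan requires a circular chromosome")
  if (max_substitutions < 0 || max_substitutions > 28)
    stopf("max_substitutions must be in [0, 28]")
  seed_seq <- if (inherits(seed, "seed_dif")) seed$sequence else toupper(seed)
  if (nchar(seed_seq) != 28L) stopf("seed must be a 28-mer")
  L <- chromosome$length
  if (L < 28L) stopf("chromosome shorter than 28 bases")

  ext <- paste0(chromosome$sequence, substr(chromosome$sequence, 1L, 27L))
  subject <- Biostrings::DNAString(ext)

  scan_one <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                     max.mismatch = max_substitutions,
                                     with.indels = FALSE, fixed = TRUE)
    starts <- Biostrings::start(hits)
    starts <- starts[starts >= 1L & starts <= L]
    if (!length(starts)) return(NULL)
    windows <- substring(ext, starts, starts + 27L)
    keep <- !grepl("N", windows, fixed = TRUE)
    starts <- starts[keep]; windows <- windows[keep]
    if (!length(starts)) return(NULL)
    matched <- if (strand == "-") reverse_complement(windows) else windows
    data.frame(chromosome = chromosome$id, start = starts, strand = strand,
               substitutions = vapply(matched, hamming, integer(1),
                                      b = seed_seq, USE.NAMES = FALSE),
               matched = matched, stringsAsFactors = FALSE)
  }

  out <- rbind(scan_one(seed_seq, "+"),
               scan_one(reverse_complement(seed_seq), "-"))
  if (is.null(out))
    out <- data.frame(chromosome = character(), start = integer(),
                      strand = character(), substitutions = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  out <- out[order(out$substitutions, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fuzzy_hits", "data.frame")
  out
}
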