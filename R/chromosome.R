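#' Circular bacterial chromosome
#'
#' Container for one chromosome: uppercase nucleotide sequence over
#' \code{A,C,G,T,N}, taxonomy labels, and gene annotations. All pipeline
#' inputs must be circular; linear records are rejected at ingest.
#'
#' @param id chromosome identifier (unique within a run).
#' @param sequence nucleotide string; lowercase is uppercased, ambiguity
#'   codes other than \code{N} are rejected.
#' @param organism organism/strain name (defaults to \code{id}); several
#'   chromosomes may share one organism.
#' @param phylum,class,genus taxonomy labels.
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param annotations data frame of gene annotations with columns
#'   \code{symbol} (\code{xerC}, \code{xerD}, \code{ftsK} or \code{other}),
#'   \code{start}, \code{end} (1-based inclusive; \code{start > end} only for
#'   origin-spanning features), \code{strand} (\code{+}/\code{-}) and
#'   \code{protein} (amino-acid string or \code{NA}).
#' @return object of class \code{chromosome} with fields \code{id},
#'   \code{organism}, \code{taxonomy}, \code{sequence}, \code{topology},
#'   \code{length} and \code{annotations}.
#' @examples
#' ch <- chromosome("c1", "acgtACGT", genus = "Escherichia")
#' ch$sequence
#' @export
chromosome <- function(id, sequence, organism = id,
                       phylum = NA_character_, class = NA_character_,
                       genus = NA_character_,
                       topology = c("circular", "linear"),
                       annotations = NULL) {
  topology <- match.arg(topology)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("chromosome '%s': sequence must be a non-empty string", id)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]),
                 c(DNA_BASES, "N"))
  if (length(bad))
    stopf("chromosome '%s': disallowed characters in sequence: %s",
          id, paste(bad, collapse = ", "))
  if (is.null(annotations)) annotations <- empty_annotations()
  annotations <- validate_annotations(annotations, nchar(sequence), id)
  structure(list(
    id = as.character(id),
    organism = as.character(organism),
    taxonomy = list(phylum = phylum, class = class, genus = genus),
    sequence = sequence,
    topology = topology,
    length = nchar(sequence),
    annotations = annotations
  ), class = "chromosome")
}

empty_annotations <- function() {
  data.frame(symbol = character(), start = integer(), end = integer(),
             strand = character(), protein = character(),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, L, id) {
  need <- c("symbol", "start", "end", "strand", "protein")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stopf("chromosome '%s': annotation table lacks columns: %s",
          id, paste(miss, collapse = ", "))
  ann <- ann[, need, drop = FALSE]
  if (nrow(ann)) {
    if (any(ann$start < 1 | ann$start > L | ann$end < 1 | ann$end > L))
      stopf("chromosome '%s': annotation coordinates outside [1, %d]", id, L)
    if (!all(ann$strand %in% c("+", "-")))
      stopf("chromosome '%s': annotation strand must be '+' or '-'", id)
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("<chromosome> %s (%s), %s, %d bp, %d annotation(s)\n",
              x$id, x$organism, x$topology, x$length, nrow(x$annotations)))
  tx <- unlist(x$taxonomy)
  cat(sprintf("  taxonomy: %s\n",
              paste(sprintf("%s=%s", names(tx), tx), collapse = " ")))
  invisible(x)
}

#' Extract XerC/XerD protein sequences from a chromosome's annotations
#'
#' @param chrom a \code{chromosome}.
#' @return list with elements \code{xerC} and \code{xerD} (amino-acid strings
#'   or \code{NA} when absent). When a symbol occurs more than once the first
#'   annotated copy is used.
#' @export
xer_proteins <- function(chrom) {
  ann <- chrom$annotations
  pick <- function(sym) {
    i <- which(ann$symbol == sym & !is.na(ann$protein) & nzchar(ann$protein))
    if (length(i)) ann$protein[i[1]] else NA_character_
  }
  list(xerC = pick("xerC"), xerD = pick("xerD"))
}

# 28-mer window read on the given strand starting at 1-based `start`
# (circular wrap-around handled)
window_at <- function(chrom, start, strand = "+", width = 28L) {
  L <- chrom$length
  idx <- wrap_pos(seq.int(start, start + width - 1L), L)
  w <- paste(strsplit(chrom$sequence, "", fixed = TRUE)[[1]][idx],
             collapse = "")
  if (strand == "-") reverse_complement(w) else w
}
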