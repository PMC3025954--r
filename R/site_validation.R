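#' Palindromic complementarity of the XerC/XerD binding arms
#'
#' The two 6-bp stretches at positions 7-12 and 17-22 of a dif 28-mer (the
#' inner halves of the XerC and XerD binding arms) pair with each other in
#' the functional site. Counts the positions i in 7..12 whose base is
#' Watson-Crick complementary to the base at position 29-i, i.e. the pairs
#' (7,22), (8,21), (9,20), (10,19), (11,18), (12,17). An \code{N} at a
#' checked position counts as non-complementary.
#'
#' @param site 28-base string.
#' @return integer count, 0-6. Invariant under reverse-complementation of
#'   the site (the checked pairing is self-mirrored).
#' @examples
#' palindrome_pairs("GGTGCGCATAATGTATATTATGTTAAAT")  # 6 (E. coli)
#' @export
palindrome_pairs <- function(site) {
  site <- toupper(site)
  if (nchar(site) != 28L) stopf("palindrome_pairs expects a 28-mer")
  b <- strsplit(site, "", fixed = TRUE)[[1]]
  i <- 7:12
  sum(b[i] != "N" & b[29 - i] == complement_base(b[i]))
}

#' Validate a scored dif candidate
#'
#' A candidate is \code{validated} when it passes all enabled checks: bit
#' score >= \code{score_threshold}, E-value < \code{evalue_threshold},
#' palindrome pairs >= \code{palindrome_min}, and circular distance to the
#' replication origin of at least \code{ori_exclusion_fraction} of the
#' genome length. It is \code{provisional} when it fails only the score /
#' E-value thresholds but passes palindrome and position (the manual-rescue
#' path); otherwise \code{rejected}. On chromosomes without visible GC skew
#' (GCSI below threshold) the position check is skipped: there is no
#' reliable origin estimate.
#'
#' @param candidate one row of \code{\link{scan_chromosome}} output (or any
#'   list with \code{chromosome}, \code{start}, \code{strand},
#'   \code{window}, \code{bit_score}, \code{e_value}).
#' @param skew \code{\link{skew_report}} for the candidate's chromosome.
#' @param config a \code{\link{dif_config}}.
#' @param method prediction method label to record.
#' @return one-row data frame of class \code{dif_prediction}: candidate
#'   fields plus \code{palindrome_pairs}, per-check logicals
#'   (\code{check_score}, \code{check_evalue}, \code{check_palindrome},
#'   \code{check_position}) and \code{status}.
#' @export
validate_candidate <- function(candidate, skew, config = dif_config(),
                               method = "profile") {
  site <- candidate$window
  pp <- palindrome_pairs(site)
  check_score <- isTRUE(candidate$bit_score >= config$score_threshold)
  check_evalue <- isTRUE(candidate$e_value < config$evalue_threshold)
  check_palindrome <- pp >= config$palindrome_min
  check_position <- if (!isTRUE(skew$skew_visible)) {
    NA  # no reliable ori/ter; check skipped
  } else {
    circ_dist(candidate$start, skew$ori, skew$length) >=
      config$ori_exclusion_fraction * skew$length
  }
  pos_ok <- is.na(check_position) || check_position
  status <- if (check_score && check_evalue && check_palindrome && pos_ok) {
    "validated"
  } else if (check_palindrome && pos_ok) {
    "provisional"
  } else {
    "rejected"
  }
  out <- data.frame(
    chromosome = candidate$chromosome, start = candidate$start,
    strand = candidate$strand, sequence = site,
    score = candidate$bit_score, evalue = candidate$e_value,
    palindrome_pairs = pp,
    check_score = check_score, check_evalue = check_evalue,
    check_palindrome = check_palindrome, check_position = check_position,
    status = status, method = method, stringsAsFactors = FALSE)
  class(out) <- c("dif_prediction", "data.frame")
  out
}
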