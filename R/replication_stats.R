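#' Cumulative GC skew at 1-bp resolution
#'
#' Position i holds the running sum of per-base contributions s(C) = +1,
#' s(G) = -1, s(A) = s(T) = s(N) = 0; the final element equals
#' count(C) - count(G).
#'
#' @param chromosome a \code{\link{chromosome}} (or bare sequence string).
#' @return numeric vector of length L.
#' @export
cumulative_skew <- function(chromosome) {
  seq <- if (inherits(chromosome, "chromosome")) chromosome$sequence
         else toupper(chromosome)
  codes <- seq_codes(seq)
  contrib <- numeric(length(codes))
  contrib[!is.na(codes) & codes == 2L] <- 1    # C
  contrib[!is.na(codes) & codes == 3L] <- -1   # G
  cumsum(contrib)
}

#' Replication origin and terminus from the cumulative GC skew
#'
#' Under the convention that the leading strand (origin to terminus on the
#' forward strand) is G-rich, the cumulative (C - G) curve decreases along
#' the first replichore: its maximum marks the origin and its minimum the
#' terminus. Because the chromosome is circular, the cumulative curve is
#' first detrended (the linear drift from any overall C/G imbalance is
#' removed so the curve closes on itself); the extrema of the detrended
#' curve are then exactly equivariant under genome rotation. Ties break at
#' the smallest coordinate. The result is only meaningful for chromosomes
#' with visible skew (see \code{\link{gcsi}}).
#'
#' @param chromosome a circular \code{\link{chromosome}}.
#' @return list with \code{ori} and \code{ter} (1-based positions).
#' @export
find_ori_ter <- function(chromosome) {
  cs <- cumulative_skew(chromosome)
  if (all(cs == 0))
    stopf("chromosome has no G or C bases; ori/ter undefined")
  L <- length(cs)
  detrended <- cs - seq_len(L) * cs[L] / L
  list(ori = which.max(detrended), ter = which.min(detrended))
}

#' GC skew index (GCSI)
#'
#' Degree-of-skew scalar combining (a) the amplitude of the one-cycle-per-
#' genome Fourier component of the windowed GC skew series, normalized by
#' its theoretical value for a unit square wave (4 / pi), and (b) the
#' absolute difference in mean skew between the two replichores delimited by
#' the cumulative-skew extrema, normalized to [0, 1]. GCSI is the geometric
#' mean of the two: 0 for skew-free sequences, 1 for a perfect square-wave
#' skew. This self-calibrated index reproduces the operational uses of
#' published indices (the 0.05 visibility threshold and monotonicity in skew
#' strength) but is not numerically identical to it.
#'
#' @param chromosome a circular \code{\link{chromosome}}.
#' @param windows number of non-overlapping windows for the skew series
#'   (default 4096; reduced with a warning when the chromosome is shorter).
#' @return non-negative scalar.
#' @export
gcsi <- function(chromosome, windows = 4096) {
  L <- chromosome$length
  if (L < windows) {
    warnf("chromosome length %d < %d windows; using %d windows", L, windows, L)
    windows <- L
  }
  codes <- seq_codes(chromosome$sequence)
  # balanced windows covering the whole genome (window k holds the
  # positions mapping to it under the L -> windows rescaling)
  idx <- pmin(windows, floor((seq_len(L) - 1) * windows / L) + 1L)
  isC <- as.numeric(!is.na(codes) & codes == 2L)
  isG <- as.numeric(!is.na(codes) & codes == 3L)
  c_counts <- rowsum(isC, idx)[, 1]
  g_counts <- rowsum(isG, idx)[, 1]
  gc_tot <- c_counts + g_counts
  # windowed skew oriented as (G - C)/(G + C): positive on the leading strand
  skew <- ifelse(gc_tot > 0, (g_counts - c_counts) / gc_tot, 0)

  ft <- stats::fft(skew)
  sa <- 2 * Mod(ft[2]) / windows       # amplitude of the 1-cycle component
  sa_norm <- min(1, sa / (4 / pi))     # unit square wave -> 1

  # replichore split at the cumulative-skew extrema
  ot <- find_ori_ter(chromosome)
  wpos <- (seq_len(windows) - 0.5) * L / windows  # window midpoints
  on_first <- if (ot$ori <= ot$ter) {
    wpos > ot$ori & wpos <= ot$ter
  } else {
    wpos > ot$ori | wpos <= ot$ter
  }
  if (!any(on_first) || all(on_first)) return(0)
  dist <- abs(mean(skew[on_first]) - mean(skew[!on_first])) / 2
  sqrt(sa_norm * min(1, dist))
}

#' Per-chromosome replication-strand summary
#'
#' @param chromosome a circular \code{\link{chromosome}}.
#' @param gcsi_threshold visibility threshold on GCSI (default 0.05).
#' @param windows passed to \code{\link{gcsi}}.
#' @return object of class \code{skew_report}: list with \code{chromosome},
#'   \code{length}, \code{ori}, \code{ter}, \code{gcsi},
#'   \code{skew_visible}, and \code{cumulative_extremes} (max, min).
#' @export
skew_report <- function(chromosome, gcsi_threshold = 0.05, windows = 4096) {
  cs <- cumulative_skew(chromosome)
  ot <- find_ori_ter(chromosome)
  g <- gcsi(chromosome, windows = windows)
  structure(list(
    chromosome = chromosome$id,
    length = chromosome$length,
    ori = ot$ori, ter = ot$ter,
    gcsi = g, skew_visible = g >= gcsi_threshold,
    cumulative_extremes = c(max = max(cs), min = min(cs))
  ), class = "skew_report")
}

#' @export
print.skew_report <- function(x, ...) {
  cat(sprintf("<skew_report> %s: ori=%d ter=%d GCSI=%.4f (%s)\n",
              x$chromosome, x$ori, x$ter, x$gcsi,
              if (x$skew_visible) "visible" else "not visible"))
  invisible(x)
}

#' Collect skew reports into a data frame
#'
#' @param skews list of \code{\link{skew_report}} objects.
#' @return data frame with one row per chromosome.
#' @export
skew_report_table <- function(skews) {
  do.call(rbind, lapply(skews, function(s) data.frame(
    chromosome = s$chromosome, length = s$length, ori = s$ori, ter = s$ter,
    gcsi = s$gcsi, skew_visible = s$skew_visible, stringsAsFactors = FALSE)))
}

#' Replichore-relative position
#'
#' Expresses a genomic position as a percentage of the replichore (half the
#' genome) measured from the antipode of the replication origin: 0% is
#' directly opposite the origin, 100% is at the origin.
#'
#' @param position 1-based position(s).
#' @param ori 1-based origin position.
#' @param L genome length.
#' @return percentage(s) in \code{[0, 100]}.
#' @export
replichore_relative <- function(position, ori, L) {
  antipode <- wrap_pos(ori + L / 2, L)
  circ_dist(position, antipode, L) / (L / 2) * 100
}

#' Compare dif positions with GC-skew terminus shift-points
#'
#' For each chromosome with visible skew, computes the replichore-relative
#' positions of the predicted dif and of the terminus shift-point, and their
#' circular separation as a percentage of genome length; then the Spearman
#' rank correlation (average ranks on ties) of (dif_rel, ter_rel) and of
#' (gcsi, separation).
#'
#' @param predictions prediction data frame (columns \code{chromosome},
#'   \code{start}; rows without a located site are dropped).
#' @param skews skew-report data frame from \code{\link{skew_report_table}}.
#' @param gcsi_threshold chromosomes with GCSI below this are excluded.
#' @return list with \code{comparisons} (data frame: chromosome, dif_rel,
#'   ter_rel, diff_percent_genome, gcsi), \code{rho_position} and
#'   \code{rho_gcsi_vs_diff} (NA with a warning when fewer than 3 usable
#'   chromosomes).
#' @export
compare_positions <- function(predictions, skews, gcsi_threshold = 0.05) {
  p <- predictions[!is.na(predictions$start), , drop = FALSE]
  m <- merge(p, skews, by = "chromosome", sort = TRUE)
  m <- m[m$gcsi >= gcsi_threshold, , drop = FALSE]
  comp <- data.frame(
    chromosome = m$chromosome,
    dif_rel = replichore_relative(m$start, m$ori, m$length),
    ter_rel = replichore_relative(m$ter, m$ori, m$length),
    diff_percent_genome = circ_dist(m$start, m$ter, m$length) / m$length * 100,
    gcsi = m$gcsi, stringsAsFactors = FALSE)
  if (nrow(comp) < 3) {
    warnf("fewer than 3 usable chromosomes; correlations undefined")
    return(list(comparisons = comp, rho_position = NA_real_,
                rho_gcsi_vs_diff = NA_real_))
  }
  safe_rho <- function(x, y) {
    if (var(x) == 0 || var(y) == 0) return(NA_real_)  # constant: undefined
    cor(x, y, method = "spearman")
  }
  list(comparisons = comp,
       rho_position = safe_rho(comp$dif_rel, comp$ter_rel),
       rho_gcsi_vs_diff = safe_rho(comp$gcsi, comp$diff_percent_genome))
}

#' Per-position conservation of a motif set
#'
#' For each of the 28 positions, the base composition of the motifs is
#' expressed as percentages of sequences and the conservation quantity is
#' the sample variance (denominator 3) of the four percentages: 2500 when a
#' position is monomorphic (composition 100/0/0/0), 0 when perfectly uniform
#' (25/25/25/25). The percent-normalized profile is variance / 2500 x 100.
#'
#' @param motifs character vector of 28-mers (>= 1).
#' @param group label recorded on the result.
#' @return object of class \code{conservation_profile}: list with
#'   \code{group}, \code{variance} (28 values), \code{percent} (28 values in
#'   [0, 100]) and \code{composition} (4 x 28 percentage matrix).
#' @examples
#' cp <- conservation_quantity(rep("GGTGCGCATAATGTATATTATGTTAAAT", 100))
#' cp$variance[1]  # 2500
#' @export
conservation_quantity <- function(motifs, group = "all") {
  motifs <- toupper(motifs)
  if (!length(motifs)) stopf("need at least one motif")
  if (any(nchar(motifs) != 28L)) stopf("all motifs must be length 28")
  codes <- vapply(motifs, seq_codes, integer(28), USE.NAMES = FALSE)
  comp <- vapply(seq_len(28), function(j)
    tabulate(codes[j, ], nbins = 4L), integer(4)) / length(motifs) * 100
  dimnames(comp) <- list(DNA_BASES, NULL)
  v <- apply(comp, 2, var)  # sample variance, denominator 3
  structure(list(group = group, variance = v, percent = v / 2500 * 100,
                 composition = comp),
            class = "conservation_profile")
}

#' Average conservation profiles across strains
#'
#' For organisms with multiple chromosomes, conservation is computed per
#' strain and the average variance is used for percent normalization.
#'
#' @param profiles list of \code{\link{conservation_profile}} objects.
#' @param group label for the averaged profile.
#' @return a \code{\link{conservation_profile}}.
#' @export
average_conservation <- function(profiles, group = "average") {
  v <- rowMeans(vapply(profiles, `[[`, numeric(28), "variance"))
  structure(list(group = group, variance = v, percent = v / 2500 * 100,
                 composition = NULL),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> group=%s\n", x$group))
  cat(sprintf("  mean conservation: %.1f%% (XerC arm 7-12: %.1f%%, XerD arm 17-22: %.1f%%)\n",
              mean(x$percent), mean(x$percent[7:12]), mean(x$percent[17:22])))
  invisible(x)
}
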