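#' Fit a 28-column dif profile
#'
#' Builds the ungapped position-specific probability model used for scanning:
#' emission(column, base) = (count + pseudocount) / (n + 4 * pseudocount).
#' Because the training motifs are a gap-free fixed-length alignment
#' (substitution-only matching by construction), insert/delete states would
#' be inert and the model reduces to 28 match states scored as log2 odds
#' against a background composition.
#'
#' @param training character vector of 28-mers over \code{A,C,G,T}, or a data
#'   frame with columns \code{id} and \code{sequence} (training provenance is
#'   then recorded).
#' @param background probability vector over \code{A,C,G,T} (default
#'   uniform). Scanning functions override this with the scanned chromosome's
#'   own composition.
#' @param pseudocount weight added per base (default 0.5); must be positive
#'   for all emissions to be positive.
#' @return object of class \code{dif_profile} with fields \code{length},
#'   \code{emissions} (4 x 28 matrix, rows A,C,G,T), \code{background},
#'   \code{pseudocount} and \code{training} (data frame id/sequence).
#' @examples
#' pr <- dif_profile(c("GGTGCGCATAATGTATATTATGTTAAAT",
#'                     "GGTGCGCATAATGTATATTATGTTAAAC"))
#' round(pr$emissions[, 28], 3)
#' @export
dif_profile <- function(training, background = rep(0.25, 4),
                        pseudocount = 0.5) {
  if (is.data.frame(training)) {
    ids <- as.character(training$id)
    seqs <- toupper(as.character(training$sequence))
  } else {
    seqs <- toupper(as.character(training))
    ids <- if (!is.null(names(training))) names(training)
           else sprintf("training_%02d", seq_along(seqs))
  }
  if (!length(seqs)) stopf("training set must be non-empty")
  if (any(nchar(seqs) != 28L))
    stopf("all training sequences must be length 28")
  if (any(grepl("[^ACGT]", seqs)))
    stopf("training sequences must be over {A,C,G,T}")
  background <- validate_background(background)
  if (pseudocount < 0) stopf("pseudocount must be non-negative")

  codes <- vapply(seqs, seq_codes, integer(28), USE.NAMES = FALSE)  # 28 x n
  counts <- vapply(seq_len(28), function(j)
    tabulate(codes[j, ], nbins = 4L), integer(4))                    # 4 x 28
  n <- length(seqs)
  emissions <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(emissions) <- list(DNA_BASES, NULL)
  structure(list(length = 28L, emissions = emissions,
                 background = background, pseudocount = pseudocount,
                 training = data.frame(id = ids, sequence = seqs,
                                       stringsAsFactors = FALSE)),
            class = "dif_profile")
}

validate_background <- function(background) {
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stopf("background must be 4 probabilities summing to 1")
  background <- as.numeric(background)
  names(background) <- DNA_BASES
  background
}

#' @export
print.dif_profile <- function(x, ...) {
  cat(sprintf("<dif_profile> 28 columns, %d training sequence(s), pseudocount %.3g\n",
              nrow(x$training), x$pseudocount))
  cat(sprintf("  consensus: %s\n", profile_consensus(x)))
  cat(sprintf("  information content: %.1f bits (vs stored background)\n",
              profile_information(x)))
  invisible(x)
}

#' @method summary dif_profile
#' @export
summary.dif_profile <- function(object, ...) {
  cat(sprintf("dif profile over %d training sequences\n",
              nrow(object$training)))
  cat(sprintf("consensus: %s\n", profile_consensus(object)))
  cat(sprintf("total information: %.2f bits\n", profile_information(object)))
  cat("per-column information (bits):\n")
  print(round(column_information(object), 2))
  invisible(object)
}

profile_consensus <- function(profile) {
  paste(DNA_BASES[apply(profile$emissions, 2, which.max)], collapse = "")
}

column_information <- function(profile, background = profile$background) {
  colSums(profile$emissions * log2(profile$emissions / background))
}

profile_information <- function(profile, background = profile$background) {
  sum(column_information(profile, background))
}

#' Plot per-column information content of a profile
#'
#' @param x a \code{\link{dif_profile}}.
#' @param ... passed to \code{barplot}.
#' @method plot dif_profile
#' @export
plot.dif_profile <- function(x, ...) {
  ic <- column_information(x)
  graphics::barplot(ic, names.arg = seq_len(28),
                    xlab = "dif position", ylab = "information (bits)",
                    main = "Profile information content", ...)
  graphics::abline(v = c(6.6, 12.4, 16.6, 22.4) * 1.2, lty = 3)
  invisible(x)
}

# 4 x 28 matrix of per-column log2-odds scores
score_matrix <- function(profile, background = profile$background,
                         floor_bits = -1000) {
  s <- log2(profile$emissions / background)
  s[!is.finite(s)] <- floor_bits  # only reachable with pseudocount 0
  s
}

#' Log-odds bit score of one 28-mer window
#'
#' Sum over columns of \code{log2(emission / background)}; additive over
#' columns. Windows containing \code{N} are unscoreable (\code{NA}).
#'
#' @param profile a \code{\link{dif_profile}}.
#' @param window 28-base string.
#' @param background background probabilities (default: the profile's).
#' @return bit score, or \code{NA} for windows containing \code{N}.
#' @export
score_window <- function(profile, window, background = profile$background) {
  window <- toupper(window)
  if (nchar(window) != 28L) stopf("window must be length 28")
  codes <- seq_codes(window)
  if (anyNA(codes)) return(NA_real_)
  background <- validate_background(background)
  s <- score_matrix(profile, background)
  sum(s[cbind(codes, seq_len(28L))])
}

#' Exact tail probability of the profile score under the background
#'
#' Computes P(score >= threshold) for a background-distributed window by
#' dynamic programming over the per-column score distribution, with scores
#' discretized to a fixed grid (default 1/1000 bit). Monotone non-increasing
#' in the threshold.
#'
#' @param profile a \code{\link{dif_profile}}.
#' @param threshold bit-score threshold.
#' @param background background probabilities (default: the profile's).
#' @param grid discretization step in bits.
#' @return probability in \code{[0, 1]}.
#' @export
score_pvalue <- function(profile, threshold, background = profile$background,
                         grid = 1e-3) {
  background <- validate_background(background)
  dist <- score_distribution(profile, background, grid)
  pvalue_from_distribution(dist, threshold)
}

# Discretized exact distribution of the window score under the background.
# Returns list(offset, prob, grid, neg_inf_mass): prob[k] is the probability
# of integer score (offset + k - 1) grid units.
score_distribution <- function(profile, background = profile$background,
                               grid = 1e-3) {
  background <- validate_background(background)
  s <- log2(profile$emissions / background)          # may contain -Inf
  finite <- is.finite(s)
  si <- matrix(0L, 4, ncol(s))
  si[finite] <- as.integer(round(s[finite] / grid))
  ncol_p <- ncol(s)

  prob <- 1
  offset <- 0L
  neg_inf_mass <- 0
  for (j in seq_len(ncol_p)) {
    fin_b <- which(finite[, j])
    if (length(fin_b) < 4) {
      inf_b <- setdiff(1:4, fin_b)
      neg_inf_mass <- neg_inf_mass + sum(background[inf_b]) * sum(prob)
    }
    if (!length(fin_b)) { prob <- numeric(0); break }
    shifts <- si[fin_b, j]
    lo <- min(shifts); hi <- max(shifts)
    new_len <- length(prob) + (hi - lo)
    acc <- numeric(new_len)
    for (k in seq_along(fin_b)) {
      at <- shifts[k] - lo
      acc[(at + 1):(at + length(prob))] <-
        acc[(at + 1):(at + length(prob))] + background[fin_b[k]] * prob
    }
    prob <- acc
    offset <- offset + lo
  }
  list(offset = offset, prob = prob, grid = grid,
       neg_inf_mass = neg_inf_mass)
}

pvalue_from_distribution <- function(dist, threshold) {
  if (!is.finite(threshold)) {
    if (threshold == -Inf) return(1)
    return(0)
  }
  k <- as.integer(round(threshold / dist$grid))
  i0 <- k - dist$offset + 1L
  # -Inf-scoring windows (possible only at pseudocount 0) never reach a
  # finite threshold, so only the finite mass contributes
  if (i0 <= 1L) return(sum(dist$prob))
  if (i0 > length(dist$prob)) return(0)
  sum(dist$prob[i0:length(dist$prob)])
}

#' Scan a circular chromosome with a dif profile
#'
#' All \code{2L} windows (both strands, wrap-around included) are scored
#' against the profile using the chromosome's own strand-symmetrized
#' mononucleotide composition as background. E-values are
#' \code{p-value x (number of scored windows)}; windows containing \code{N}
#' are not scored.
#'
#' @param profile a \code{\link{dif_profile}}.
#' @param chromosome a circular \code{\link{chromosome}} (length >= 28).
#' @param reporting_evalue hits with E-value at or below this ceiling are
#'   returned in addition to the best hit (default 10).
#' @param grid p-value discretization grid in bits.
#' @return data frame of class \code{scan_hits}, sorted by descending bit
#'   score (ties: lowest start, then + strand), with columns
#'   \code{chromosome}, \code{start}, \code{strand}, \code{window},
#'   \code{bit_score}, \code{p_value}, \code{e_value}, and attribute
#'   \code{n_windows}.
#' @export
scan_chromosome <- function(profile, chromosome, reporting_evalue = 10,
                            grid = 1e-3) {
  if (!inherits(chromosome, "chromosome"))
    stopf("scan_chromosome expects a chromosome object")
  if (chromosome$topology != "circular")
    stopf("scan_chromosome requires a circular chromosome")
  L <- chromosome$length
  if (L < 28L) stopf("chromosome shorter than 28 bases")

  codes <- seq_codes(chromosome$sequence)
  codes_ext <- c(codes, codes[seq_len(27L)])
  background <- chromosome_background(codes)
  s <- score_matrix(profile, background)

  # forward-strand windows: column j aligns to genome position start+j-1
  fwd <- numeric(L)
  # reverse-strand windows at the same footprint: the window read 5'-3' on
  # the minus strand puts motif column j on complement(position start+28-j)
  scomp <- s[c(4L, 3L, 2L, 1L), 28L:1L]  # scomp[b, j] = s[comp(b), 29-j]
  rev <- numeric(L)
  na_mask <- logical(L)
  for (j in seq_len(28L)) {
    cj <- codes_ext[j:(j + L - 1L)]
    na_mask <- na_mask | is.na(cj)
    cj_safe <- ifelse(is.na(cj), 1L, cj)
    fwd <- fwd + s[cbind(cj_safe, j)]
    rev <- rev + scomp[cbind(cj_safe, j)]
  }
  fwd[na_mask] <- NA_real_
  rev[na_mask] <- NA_real_
  n_windows <- 2L * sum(!na_mask)

  dist <- score_distribution(profile, background, grid)
  sf_lookup <- function(score) {
    vapply(score, function(x) pvalue_from_distribution(dist, x), numeric(1))
  }

  hits <- data.frame(
    chromosome = chromosome$id,
    start = rep(seq_len(L), 2L),
    strand = rep(c("+", "-"), each = L),
    bit_score = c(fwd, rev),
    stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$bit_score), , drop = FALSE]
  # rank without computing p-values for every window
  strand_rank <- ifelse(hits$strand == "+", 0L, 1L)
  ord <- order(-hits$bit_score, hits$start, strand_rank)
  hits <- hits[ord, , drop = FALSE]

  pv <- pvalue_from_distribution_vec(dist, hits$bit_score)
  ev <- pv * n_windows
  keep <- ev <= reporting_evalue
  if (any(!keep)) keep[1L] <- TRUE  # always report the best hit
  hits <- hits[keep, , drop = FALSE]
  pv <- pv[keep]; ev <- ev[keep]

  ext <- paste0(chromosome$sequence, substr(chromosome$sequence, 1L, 27L))
  win <- substring(ext, hits$start, hits$start + 27L)
  minus <- hits$strand == "-"
  if (any(minus)) win[minus] <- reverse_complement(win[minus])
  hits$window <- win
  hits$p_value <- pv
  hits$e_value <- ev
  hits <- hits[, c("chromosome", "start", "strand", "window",
                   "bit_score", "p_value", "e_value")]
  rownames(hits) <- NULL
  attr(hits, "n_windows") <- n_windows
  attr(hits, "background") <- background
  class(hits) <- c("scan_hits", "data.frame")
  hits
}

pvalue_from_distribution_vec <- function(dist, scores) {
  n <- length(dist$prob)
  if (!n) return(rep(0, length(scores)))
  sf <- rev(cumsum(rev(dist$prob)))  # sf[i] = P(int score >= offset + i - 1)
  k <- as.integer(round(scores / dist$grid))
  i0 <- k - dist$offset + 1L
  out <- numeric(length(scores))
  out[i0 <= 1L] <- sf[1L]
  inb <- i0 > 1L & i0 <= n
  out[inb] <- sf[i0[inb]]
  out
}

# strand-symmetrized mononucleotide background of a chromosome
chromosome_background <- function(codes) {
  counts <- tabulate(codes[!is.na(codes)], nbins = 4L)
  if (sum(counts) == 0) stopf("chromosome contains no unambiguous bases")
  f <- counts / sum(counts)
  sym <- (f + f[c(4L, 3L, 2L, 1L)]) / 2  # average with complement strand
  names(sym) <- DNA_BASES
  sym
}

#' @export
predict.dif_profile <- function(object, chromosome, ...) {
  scan_chromosome(object, chromosome, ...)
}

#' Leave-one-out cross-validation of a training set
#'
#' For each training motif, a profile is fit from all the others and its
#' source chromosome re-scanned; the motif passes when the best hit falls at
#' its recorded location and strand with bit score at or above
#' \code{score_threshold} and E-value below \code{evalue_threshold}. The set
#' passes only when every motif passes.
#'
#' @param training data frame with columns \code{id}, \code{sequence},
#'   \code{chromosome}, \code{start}, \code{strand} (>= 2 rows).
#' @param chromosomes named list of \code{\link{chromosome}} objects covering
#'   \code{training$chromosome}.
#' @param score_threshold,evalue_threshold validation thresholds
#'   (defaults 10 bits, 1e-4).
#' @param pseudocount profile pseudocount.
#' @return list with \code{pass} (overall), \code{results} (per-sequence data
#'   frame: id, pass, best_start, best_strand, bit_score, e_value).
#' @export
loocv <- function(training, chromosomes, score_threshold = 10,
                  evalue_threshold = 1e-4, pseudocount = 0.5) {
  if (nrow(training) < 2) {
    warnf("LOOCV skipped: training set has fewer than 2 sequences")
    return(list(pass = NA, results = NULL))
  }
  res <- lapply(seq_len(nrow(training)), function(i) {
    held <- training[i, ]
    prof <- dif_profile(training[-i, c("id", "sequence")],
                        pseudocount = pseudocount)
    chrom <- chromosomes[[held$chromosome]]
    hits <- scan_chromosome(prof, chrom)
    best <- hits[1, ]
    pass <- best$start == held$start && best$strand == held$strand &&
      best$bit_score >= score_threshold && best$e_value < evalue_threshold
    data.frame(id = held$id, pass = pass, best_start = best$start,
               best_strand = best$strand, bit_score = best$bit_score,
               e_value = best$e_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  list(pass = all(res$pass), results = res)
}

#' Write / read a dif profile as a tabular text file
#'
#' Format: metadata header lines (\code{# key: value}) followed by a TSV of
#' \code{column}, \code{base}, \code{probability} with full-precision
#' numbers; round-trips exactly.
#'
#' @param profile a \code{\link{dif_profile}}.
#' @param path output file.
#' @return \code{write_profile}: the path, invisibly. \code{read_profile}:
#'   the restored \code{dif_profile}.
#' @export
write_profile <- function(profile, path) {
  hdr <- c("# difscan profile v1",
           sprintf("# pseudocount: %s",
                   format(profile$pseudocount, digits = 17)),
           sprintf("# background: %s",
                   paste(format(profile$background, digits = 17),
                         collapse = ",")),
           sprintf("# training: %s",
                   paste(profile$training$id, profile$training$sequence,
                         sep = ":", collapse = ",")))
  body <- sprintf("%d\t%s\t%s",
                  rep(seq_len(28L), each = 4L),
                  rep(DNA_BASES, 28L),
                  format(as.vector(profile$emissions), digits = 17))
  writeLines(c(hdr, "column\tbase\tprobability", body), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# difscan profile v1"))
    stopf("not a difscan profile file: %s", path)
  meta <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), lines, value = TRUE))
  pseudocount <- as.numeric(meta("pseudocount"))
  background <- as.numeric(strsplit(meta("background"), ",")[[1]])
  tr <- strsplit(strsplit(meta("training"), ",")[[1]], ":")
  training <- data.frame(id = vapply(tr, `[`, "", 1),
                         sequence = vapply(tr, `[`, "", 2),
                         stringsAsFactors = FALSE)
  body <- lines[-seq_len(grep("^column\tbase", lines)[1])]
  parts <- strsplit(body, "\t", fixed = TRUE)
  em <- matrix(NA_real_, 4, 28, dimnames = list(DNA_BASES, NULL))
  for (p in parts)
    em[p[2], as.integer(p[1])] <- as.numeric(p[3])
  structure(list(length = 28L, emissions = em,
                 background = validate_background(background),
                 pseudocount = pseudocount, training = training),
            class = "dif_profile")
}
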