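# Independent oracles and small fixture builders, used across test files.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

rand_chromosome <- function(n, seed, id = "rand", ...) {
  chromosome(id, rand_seq(n, seed), ...)
}

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# place a motif at a 1-based start (wrapping) on the given strand
place_motif <- function(sequence, motif, start, strand = "+") {
  L <- nchar(sequence)
  written <- if (strand == "-") rc_oracle(motif) else motif
  b <- strsplit(sequence, "")[[1]]
  idx <- ((seq.int(start, start + nchar(motif) - 1) - 1) %% L) + 1
  b[idx] <- strsplit(written, "")[[1]]
  paste(b, collapse = "")
}

# mutate exactly k distinct positions of a motif to a different base
mutate_k <- function(motif, k, seed) {
  set.seed(seed)
  b <- strsplit(motif, "")[[1]]
  for (i in sample(length(b), k))
    b[i] <- sample(setdiff(BASES, b[i]), 1)
  paste(b, collapse = "")
}

# brute-force substitution-only scan: walk the doubled sequence on both
# strands with substring comparisons, deduplicate modulo L
brute_fuzzy_scan <- function(sequence, seed28, max_sub) {
  L <- nchar(sequence)
  doubled <- paste0(sequence, sequence)
  out <- list()
  for (start in seq_len(L)) {
    w <- substr(doubled, start, start + 27)
    if (grepl("N", w, fixed = TRUE)) next
    for (strand in c("+", "-")) {
      m <- if (strand == "-") rc_oracle(w) else w
      d <- sum(strsplit(m, "")[[1]] != strsplit(seed28, "")[[1]])
      if (d <= max_sub)
        out[[length(out) + 1]] <- data.frame(
          start = start, strand = strand, substitutions = d, matched = m,
          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(out, list(NULL)))
  if (is.null(df)) return(data.frame(start = integer(), strand = character(),
                                     substitutions = integer(),
                                     matched = character()))
  df <- df[order(df$substitutions, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# vectorized variant of the doubled-sequence oracle for larger genomes:
# plain character-vector mismatch accumulation, no Biostrings
brute_fuzzy_scan_fast <- function(sequence, seed28, max_sub) {
  L <- nchar(sequence)
  chars <- strsplit(paste0(sequence, substr(sequence, 1, 27)), "")[[1]]
  count_mism <- function(pattern) {
    pc <- strsplit(pattern, "")[[1]]
    mism <- integer(L)
    hasN <- logical(L)
    for (j in 1:28) {
      seg <- chars[j:(j + L - 1)]
      mism <- mism + (seg != pc[j])
      hasN <- hasN | seg == "N"
    }
    mism[hasN] <- NA_integer_
    mism
  }
  res <- list()
  for (strand in c("+", "-")) {
    patt <- if (strand == "-") rc_oracle(seed28) else seed28
    mism <- count_mism(patt)
    ok <- which(!is.na(mism) & mism <= max_sub)
    if (length(ok)) {
      w <- substring(paste(chars, collapse = ""), ok, ok + 27)
      m <- if (strand == "-") vapply(w, rc_oracle, "", USE.NAMES = FALSE)
           else w
      res[[strand]] <- data.frame(start = ok, strand = strand,
                                  substitutions = mism[ok], matched = m,
                                  stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(res, list(NULL)))
  if (is.null(df)) return(data.frame(start = integer(), strand = character(),
                                     substitutions = integer(),
                                     matched = character()))
  df <- df[order(df$substitutions, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# palindrome oracle: compare the 7-12 stretch to the reversed complement of
# the 17-22 stretch, base by base
brute_palindrome <- function(site) {
  a <- strsplit(substr(site, 7, 12), "")[[1]]
  b <- strsplit(rc_oracle(substr(site, 17, 22)), "")[[1]]
  sum(a != "N" & b != "N" & a == b)
}

# toy profile over k columns (bypasses the 28-column constructor)
toy_profile <- function(emissions, background = rep(0.25, 4)) {
  rownames(emissions) <- BASES
  structure(list(length = ncol(emissions), emissions = emissions,
                 background = structure(background, names = BASES),
                 pseudocount = 0,
                 training = data.frame(id = character(),
                                       sequence = character())),
            class = "dif_profile")
}

# exhaustive p-value for a toy profile: enumerate all 4^k windows
enum_pvalue <- function(emissions, background, threshold) {
  k <- ncol(emissions)
  grid <- expand.grid(rep(list(1:4), k))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    codes <- as.integer(grid[r, ])
    sc <- sum(log2(emissions[cbind(codes, seq_len(k))] / background[codes]))
    if (sc >= threshold) total <- total + prod(background[codes])
  }
  total
}

# thresholds lying in clear gaps between achievable toy-profile scores, so
# that an eps-discretized DP and the exact enumeration classify every window
# identically
gap_thresholds <- function(emissions, background, n = 3, min_gap = 0.02) {
  k <- ncol(emissions)
  grid <- expand.grid(rep(list(1:4), k))
  scores <- sort(unique(vapply(seq_len(nrow(grid)), function(r) {
    codes <- as.integer(grid[r, ])
    sum(log2(emissions[cbind(codes, seq_len(k))] / background[codes]))
  }, numeric(1))))
  gaps <- diff(scores)
  ok <- which(gaps > min_gap)
  ok <- ok[order(-gaps[ok])][seq_len(min(n, length(ok)))]
  c(scores[1] - 1, (scores[ok] + scores[ok + 1]) / 2,
    scores[length(scores)] + 1)
}

# textbook Spearman coefficient for distinct ranks: 1 - 6*sum(d^2)/(n(n^2-1))
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# small ready-made study for pipeline tests (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- clade_spec(n_genera = 3, genomes_per_genus = 3,
                         genome_length = 20000, random_seed = 7)
      cache <<- evolve_clade(spec)
    }
    cache
  }
})
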