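#' @importFrom stats cor runif var
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# circular distance between two coordinates on a ring of size L
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# wrap a (possibly real) coordinate onto 1..L
wrap_pos <- function(p, L) {
  ((p - 1) %% L) + 1
}

reverse_complement <- function(x) {
  rc <- chartr("ACGTN", "TGCAN", x)
  vapply(rc, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# integer codes A=1 C=2 G=3 T=4, N -> NA
seq_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed derivation (kept within 32-bit signed range)
derive_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "")
}

# fixed-format numbers for byte-stable reports
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = digits))
}
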