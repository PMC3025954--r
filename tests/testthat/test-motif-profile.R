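ecoli_seq <- published_seeds()$e_coli$sequence

test_that("profile emissions follow the add-pseudocount formula", {
  # degenerate: single training sequence, zero pseudocount
  pA <- dif_profile(strrep("A", 28), pseudocount = 0)
  expect_true(all(pA$emissions["A", ] == 1))
  expect_true(all(pA$emissions[c("C", "G", "T"), ] == 0))

  # counting: two sequences differing at column 1 only
  p2 <- dif_profile(c(strrep("A", 28), paste0("C", strrep("A", 27))),
                    pseudocount = 0)
  expect_equal(unname(p2$emissions[, 1]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(p2$emissions[, 2]), c(1, 0, 0, 0))

  # pseudocount arithmetic: n=2, count A=2, pc=0.5 -> 2.5/4
  p3 <- dif_profile(rep(strrep("A", 28), 2), pseudocount = 0.5)
  expect_equal(unname(p3$emissions["A", 1]), 0.625)
  expect_equal(unname(colSums(p3$emissions)), rep(1, 28))

  # order independence
  tr <- c(ecoli_seq, mutate_k(ecoli_seq, 3, 1), mutate_k(ecoli_seq, 5, 2))
  expect_equal(dif_profile(tr)$emissions, dif_profile(rev(tr))$emissions)

  expect_error(dif_profile("ACGT"), "length 28")
})

test_that("window bit scores have the closed forms and are additive", {
  pA <- dif_profile(strrep("A", 28), pseudocount = 0)
  expect_equal(score_window(pA, strrep("A", 28)), 28 * log2(1 / 0.25))

  # emissions equal to background -> 0 bits for every window
  punif <- toy_profile(matrix(0.25, 4, 28))
  for (seed in 1:3)
    expect_equal(score_window(punif, rand_seq(28, seed)), 0)

  # additivity: score equals the sum of independent per-column scores
  pr <- dif_profile(c(ecoli_seq, mutate_k(ecoli_seq, 4, 3)))
  w <- rand_seq(28, 99)
  percol <- vapply(1:28, function(j) {
    base <- substr(w, j, j)
    log2(pr$emissions[base, j] / pr$background[base])
  }, numeric(1))
  expect_equal(score_window(pr, w), sum(percol))

  expect_true(is.na(score_window(pr, paste0("N", substr(w, 2, 28)))))
})

test_that("p-value DP matches exhaustive enumeration on toy profiles", {
  set.seed(5)
  for (k in 4:6) {
    em <- matrix(rgamma(4 * k, 1), 4, k)
    em <- sweep(em, 2, colSums(em), "/")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    pr <- toy_profile(em, bg)
    # thresholds in clear gaps between achievable scores, plus the extremes
    smin <- sum(apply(log2(em / bg), 2, min))
    smax <- sum(apply(log2(em / bg), 2, max))
    for (t in gap_thresholds(em, bg)) {
      expect_equal(score_pvalue(pr, t, background = bg),
                   enum_pvalue(em, bg, t), tolerance = 1e-9)
    }
    expect_equal(score_pvalue(pr, smin - 1, background = bg), 1)
    expect_equal(score_pvalue(pr, smax + 1, background = bg), 0)
    # total probability over the full window space is 1
    d <- difscan:::score_distribution(pr, bg)
    expect_equal(sum(d$prob) + d$neg_inf_mass, 1, tolerance = 1e-12)
  }
})

test_that("p-value is monotone and stable under 10x grid refinement", {
  pr <- dif_profile(c(ecoli_seq, mutate_k(ecoli_seq, 2, 7)))
  ts <- seq(-10, 40, by = 5)
  pv <- vapply(ts, function(t) score_pvalue(pr, t), numeric(1))
  expect_true(all(diff(pv) <= 0))
  set.seed(8)
  em <- matrix(rgamma(20, 1), 4, 5); em <- sweep(em, 2, colSums(em), "/")
  tp <- toy_profile(em)
  for (t in c(0, 2, 4)) {
    p1 <- score_pvalue(tp, t, grid = 1e-3)
    p2 <- score_pvalue(tp, t, grid = 1e-4)
    expect_lt(abs(p1 - p2), 0.05 * max(p2, 1e-300))
  }
})

test_that("scanning finds an implanted motif as the top hit on both strands", {
  pr <- dif_profile(c(ecoli_seq, mutate_k(ecoli_seq, 2, 11),
                      mutate_k(ecoli_seq, 3, 12)))
  for (strand in c("+", "-")) {
    ch <- chromosome("s", place_motif(rand_seq(30000, 61), ecoli_seq,
                                      12345, strand))
    hits <- scan_chromosome(pr, ch)
    expect_identical(hits$start[1], 12345L)
    expect_identical(hits$strand[1], strand)
    expect_equal(hits$e_value[1], hits$p_value[1] * attr(hits, "n_windows"))
  }
})

test_that("scanning the reverse-complemented chromosome mirrors the hit", {
  pr <- dif_profile(c(ecoli_seq, mutate_k(ecoli_seq, 2, 13)))
  seqn <- place_motif(rand_seq(20000, 62), ecoli_seq, 777)
  L <- nchar(seqn)
  h1 <- scan_chromosome(pr, chromosome("f", seqn))[1, ]
  h2 <- scan_chromosome(pr, chromosome("r", rc_oracle(seqn)))[1, ]
  expect_identical(h2$start, as.integer(L - (h1$start + 27) + 1))
  expect_identical(h2$strand, "-")
  expect_equal(h2$bit_score, h1$bit_score)
})

test_that("a background-equal profile yields no hits above threshold", {
  punif <- toy_profile(matrix(0.25, 4, 28))
  ch <- chromosome("u", strrep("ACGT", 2500))  # exactly uniform composition
  hits <- scan_chromosome(punif, ch)
  expect_true(all(abs(hits$bit_score) < 1e-9))
  expect_false(any(hits$bit_score >= 10))
})

test_that("wrap-around windows are scored", {
  pr <- dif_profile(c(ecoli_seq, mutate_k(ecoli_seq, 1, 14)))
  start <- 10000 - 12
  ch <- chromosome("w", place_motif(rand_seq(10000, 63), ecoli_seq, start))
  hits <- scan_chromosome(pr, ch)
  expect_identical(hits$start[1], as.integer(start))
})

make_loocv_set <- function(n, motif, genome_len = 15000, seed0 = 100) {
  rows <- list(); chroms <- list()
  for (i in seq_len(n)) {
    m <- if (i == 1) motif else mutate_k(motif, 2, seed0 + i)
    start <- 2000 + 997 * i
    ch <- chromosome(paste0("lc", i),
                     place_motif(rand_seq(genome_len, seed0 + i), m, start))
    chroms[[ch$id]] <- ch
    rows[[i]] <- data.frame(id = ch$id, sequence = m, chromosome = ch$id,
                            start = start, strand = "+",
                            stringsAsFactors = FALSE)
  }
  list(training = do.call(rbind, rows), chromosomes = chroms)
}

test_that("LOOCV passes a self-consistent set and fails an unrelated motif", {
  s <- make_loocv_set(6, ecoli_seq)
  cv <- loocv(s$training, s$chromosomes)
  expect_true(cv$pass)
  expect_true(all(cv$results$pass))

  # replace one member with a random unrelated 28-mer
  bad <- s
  bad$training$sequence[4] <- rand_seq(28, 999)
  bad$chromosomes[[bad$training$chromosome[4]]] <- chromosome(
    bad$training$chromosome[4],
    place_motif(rand_seq(15000, 500), bad$training$sequence[4],
                bad$training$start[4]))
  cv2 <- loocv(bad$training, bad$chromosomes)
  expect_false(cv2$pass)
  expect_false(cv2$results$pass[4])
  expect_true(all(cv2$results$pass[-4]))

  # order invariance
  perm <- sample(nrow(s$training))
  cv3 <- loocv(s$training[perm, ], s$chromosomes)
  expect_identical(sort(cv3$results$id[cv3$results$pass]),
                   sort(cv$results$id[cv$results$pass]))

  expect_warning(skip1 <- loocv(s$training[1, , drop = FALSE],
                                s$chromosomes),
                 "fewer than 2")
  expect_true(is.na(skip1$pass))
})

test_that("profile serialization round-trips exactly", {
  pr <- dif_profile(data.frame(id = c("a", "b"),
                               sequence = c(ecoli_seq,
                                            mutate_k(ecoli_seq, 6, 21))),
                    background = c(0.3, 0.2, 0.2, 0.3), pseudocount = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_profile(pr, path)
  back <- read_profile(path)
  expect_identical(back$emissions, pr$emissions)
  expect_identical(back$background, pr$background)
  expect_identical(back$pseudocount, pr$pseudocount)
  expect_identical(back$training, pr$training)
})
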