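test_that("cumulative skew has its closed forms and counting identity", {
  expect_equal(cumulative_skew("GGGG"), c(-1, -2, -3, -4))
  expect_equal(cumulative_skew("GCGC"), c(-1, 0, -1, 0))
  for (i in 1:10) {
    s <- rand_seq(500, i)
    cs <- cumulative_skew(s)
    b <- strsplit(s, "")[[1]]
    expect_equal(cs[length(cs)], sum(b == "C") - sum(b == "G"))
  }
})

test_that("ori/ter of the G-then-C square wave and rotation equivariance", {
  sq <- chromosome("sq", paste0(strrep("G", 500), strrep("C", 500)))
  ot <- find_ori_ter(sq)
  expect_identical(ot$ter, 500L)
  expect_identical(ot$ori, 1000L)

  rotate <- function(s, r) paste0(substr(s, r + 1, nchar(s)),
                                  substr(s, 1, r))
  base <- rand_seq(5000, 77, prob = c(0.2, 0.35, 0.25, 0.2))
  ot0 <- find_ori_ter(chromosome("r0", base))
  set.seed(3)
  for (r in sample(4999, 5)) {
    otr <- find_ori_ter(chromosome("rr", rotate(base, r)))
    expect_identical(otr$ori, as.integer(((ot0$ori - r - 1) %% 5000) + 1))
    expect_identical(otr$ter, as.integer(((ot0$ter - r - 1) %% 5000) + 1))
  }

  expect_error(find_ori_ter(chromosome("at", strrep("AT", 50))), "undefined")
})

test_that("GCSI calibration: square wave near 1, null genomes invisible", {
  sq <- chromosome("sq", paste0(strrep("G", 5000), strrep("C", 5000)))
  expect_equal(suppressWarnings(gcsi(sq)), 1, tolerance = 0.02)

  # i.i.d. genomes have no visible skew (fuller replication in acceptance)
  vals <- vapply(1:10, function(i)
    gcsi(rand_chromosome(50000, 300 + i)), numeric(1))
  expect_gte(sum(vals < 0.05), 9)
})

test_that("GCSI grows with generator skew strength and is strand/rotation stable", {
  g_at <- function(s, seed) gcsi(generate_skewed_genome(
    50000, 0.5, s, ori = 1, seed = seed))
  m0 <- mean(vapply(1:5, function(i) g_at(0, i), numeric(1)))
  m2 <- mean(vapply(1:5, function(i) g_at(0.2, i), numeric(1)))
  m5 <- mean(vapply(1:5, function(i) g_at(0.5, i), numeric(1)))
  m10 <- mean(vapply(1:5, function(i) g_at(1.0, i), numeric(1)))
  expect_true(m0 < m2 && m2 < m5 && m5 < m10)

  ch <- generate_skewed_genome(50000, 0.5, 0.5, ori = 12000, seed = 9)
  g1 <- gcsi(ch)
  g2 <- gcsi(chromosome("rc", rc_oracle(ch$sequence)))
  expect_equal(g1, g2, tolerance = 0.02)
  rot <- paste0(substr(ch$sequence, 20001, 50000),
                substr(ch$sequence, 1, 20000))
  expect_equal(g1, gcsi(chromosome("rot", rot)), tolerance = 0.02)
})

test_that("replichore-relative positions match the figure conventions", {
  L <- 100000; ori <- 10000
  antipode <- ori + L / 2
  expect_equal(replichore_relative(antipode, ori, L), 0)
  expect_equal(replichore_relative(ori, ori, L), 100)
  expect_equal(replichore_relative(ori + L / 4, ori, L), 50)
  expect_equal(replichore_relative(ori - L / 4, ori, L), 50)
})

test_that("position comparison: collinearity, Spearman oracle, exclusions", {
  skews <- do.call(rbind, lapply(1:6, function(i) data.frame(
    chromosome = paste0("c", i), length = 100000L, ori = 1000L * i,
    ter = 1000L * i + 50000L + 900L * i, gcsi = ifelse(i == 6, 0.01, 0.2),
    skew_visible = i != 6, stringsAsFactors = FALSE)))
  preds <- data.frame(chromosome = paste0("c", 1:6),
                      start = skews$ter + 120L * (1:6),
                      stringsAsFactors = FALSE)
  out <- compare_positions(preds, skews, gcsi_threshold = 0.05)
  expect_identical(nrow(out$comparisons), 5L)  # c6 excluded by GCSI
  expect_true(all(out$comparisons$diff_percent_genome <= 50))
  expect_gt(out$rho_position, 0.99)
  # textbook rank-formula oracle on the same pairs (all ranks distinct)
  expect_equal(out$rho_position,
               spearman_formula(out$comparisons$dif_rel,
                                out$comparisons$ter_rel))

  expect_warning(u <- compare_positions(preds[1:2, ], skews[1:2, ]),
                 "fewer than 3")
  expect_true(is.na(u$rho_position))
})

test_that("dif exactly at ter gives rho 1 and zero separation", {
  skews <- do.call(rbind, lapply(1:5, function(i) data.frame(
    chromosome = paste0("t", i), length = 50000L, ori = 500L * i,
    ter = 500L * i + 25000L + 700L * i, gcsi = 0.3, skew_visible = TRUE,
    stringsAsFactors = FALSE)))
  preds <- data.frame(chromosome = paste0("t", 1:5), start = skews$ter)
  out <- compare_positions(preds, skews)
  expect_equal(out$rho_position, 1)
  expect_true(all(out$comparisons$diff_percent_genome == 0))
})

test_that("conservation quantity reproduces the worked examples", {
  # monomorphic position: composition 100/0/0/0 -> variance 2500 -> 100%
  mono <- conservation_quantity(rep(strrep("A", 28), 100))
  expect_equal(unname(mono$variance), rep(2500, 28))
  expect_equal(unname(mono$percent), rep(100, 28))

  # perfectly uniform position -> variance 0 -> 0%
  unif <- conservation_quantity(c(strrep("A", 28), strrep("C", 28),
                                  strrep("G", 28), strrep("T", 28)))
  expect_equal(unname(unif$variance), rep(0, 28))

  # 50/50 split: variance 2500/3
  half <- conservation_quantity(c(strrep("A", 28), strrep("C", 28)))
  expect_equal(unname(half$variance), rep(2500 / 3, 28))
  expect_equal(unname(half$percent), rep(100 / 3, 28))
})

test_that("conservation percent is bounded with the right extremes", {
  set.seed(12)
  motifs <- replicate(40, rand_seq(28, sample.int(1e6, 1)))
  cp <- conservation_quantity(motifs)
  expect_true(all(cp$percent >= 0 & cp$percent <= 100))
  # 100 iff monomorphic
  expect_false(any(cp$percent == 100))
  avg <- average_conservation(list(cp, conservation_quantity(motifs[1:10])))
  expect_length(avg$percent, 28)
})
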