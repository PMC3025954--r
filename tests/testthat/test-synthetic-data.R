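test_that("skewed-genome generator honours composition and determinism", {
  ch1 <- generate_skewed_genome(100000, gc = 0.5, skew_strength = 0.3,
                                seed = 5)
  ch2 <- generate_skewed_genome(100000, gc = 0.5, skew_strength = 0.3,
                                seed = 5)
  expect_identical(ch1$sequence, ch2$sequence)
  b <- strsplit(ch1$sequence, "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  expect_error(generate_skewed_genome(50000, gc = 0.5, skew_strength = 1.5),
               "skew_strength")
})

test_that("programmed terminus is recovered from strong skew", {
  for (seed in 1:3) {
    ter_true <- 30000
    ch <- generate_skewed_genome(100000, 0.5, 1, ori = 80000, ter = ter_true,
                                 seed = seed)
    ot <- find_ori_ter(ch)
    expect_lt(circ_dist(ot$ter, ter_true, 100000), 1000)  # within 1% of L
    expect_lt(circ_dist(ot$ori, 80000, 100000), 1000)
  }
})

test_that("skewless genomes look like the null", {
  vals <- vapply(1:10, function(i)
    gcsi(generate_skewed_genome(50000, 0.5, 0, seed = 400 + i)), numeric(1))
  expect_gte(sum(vals < 0.05), 9)
})

test_that("clade evolution: zero rate preserves the root dif everywhere", {
  spec <- clade_spec(n_genera = 2, genomes_per_genus = 2,
                     genome_length = 10000, motif_sub_rate = 0,
                     random_seed = 3)
  st <- evolve_clade(spec)
  expect_true(all(st$truth$implant_seq == spec$root_dif))
})

test_that("clade truth is internally consistent", {
  st <- small_study()
  L <- st$genomes[[1]]$length
  for (i in seq_len(nrow(st$truth))) {
    tr <- st$truth[i, ]
    ch <- st$genomes[[tr$chromosome]]
    # implant really is written at the recorded location and strand
    w <- difscan:::window_at(ch, tr$implant_start, tr$implant_strand)
    expect_identical(w, tr$implant_seq)
    # implant within the jitter bound of the true terminus
    expect_lte(circ_dist(tr$implant_start, tr$true_ter, L), 0.02 * L + 1)
    # genomes carry both recombinase proteins
    pr <- xer_proteins(ch)
    expect_false(is.na(pr$xerC) || is.na(pr$xerD))
  }
  # every generator output passes the chromosome invariants by construction
  expect_true(all(vapply(st$genomes, function(g)
    g$length == nchar(g$sequence) && g$topology == "circular", logical(1))))
})

test_that("deterministic regeneration and seed sensitivity", {
  spec <- clade_spec(n_genera = 2, genomes_per_genus = 2,
                     genome_length = 10000, random_seed = 11)
  a <- evolve_clade(spec)
  b <- evolve_clade(spec)
  expect_identical(lapply(a$genomes, `[[`, "sequence"),
                   lapply(b$genomes, `[[`, "sequence"))
  expect_identical(a$truth, b$truth)
  spec2 <- spec; spec2$random_seed <- 12
  c <- evolve_clade(spec2)
  expect_false(identical(a$genomes[[1]]$sequence, c$genomes[[1]]$sequence))
})

test_that("XerD arm stays more conserved than the XerC arm", {
  spec <- clade_spec(n_genera = 4, genomes_per_genus = 5,
                     genome_length = 10000, motif_sub_rate = 0.08,
                     xerD_arm_rate_factor = 0.3, pair_compensation = 0,
                     random_seed = 21)
  st <- evolve_clade(spec)
  cp <- conservation_quantity(st$truth$implant_seq)
  expect_gt(mean(cp$percent[17:22]), mean(cp$percent[7:12]))
  expect_gt(mean(cp$percent[13:28]), mean(cp$percent[1:12]))
})

test_that("study bundles round-trip through genome_io", {
  dir <- tempfile("study")
  spec <- clade_spec(n_genera = 2, genomes_per_genus = 2,
                     genome_length = 10000, negative_fraction = 0.25,
                     random_seed = 31)
  bundle <- make_study(spec, dir)
  expect_true(file.exists(bundle$seed_path))
  genomes <- read_genomes(bundle$genome_paths,
                          annotation_table = bundle$annotation_path)
  expect_length(genomes, 4)
  for (id in names(bundle$study$genomes)) {
    expect_identical(genomes[[id]]$sequence,
                     bundle$study$genomes[[id]]$sequence)
    expect_identical(genomes[[id]]$taxonomy,
                     bundle$study$genomes[[id]]$taxonomy)
    expect_identical(xer_proteins(genomes[[id]]),
                     xer_proteins(bundle$study$genomes[[id]]))
  }
  # negative-control flag leaves genomes implant-free, marked in truth
  truth <- read.delim(bundle$truth_path)
  expect_identical(sum(!truth$implanted), 1L)

  # refusal to clobber an existing bundle
  expect_error(make_study(spec, dir), "overwrite")

  # byte-identical regeneration under the same seed
  dir2 <- tempfile("study2")
  make_study(spec, dir2)
  f1 <- sort(list.files(dir, recursive = TRUE))
  expect_identical(f1, sort(list.files(dir2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
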