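genbank_fixture <- function(seq = rand_seq(1000, 11), topology = "circular",
                            id = "TESTCHR1") {
  blocks <- c(
    sprintf("LOCUS       %s             %d bp    DNA     %s BCT 01-JAN-2000",
            id, nchar(seq), topology),
    "DEFINITION  Test organism chromosome.",
    "  ORGANISM  Testus exemplaris",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             51..950",
    "                     /gene=\"xerC\"",
    "                     /product=\"tyrosine recombinase XerC\"",
    "                     /translation=\"MKTWLERFLT\"",
    "     CDS             complement(100..400)",
    "                     /product=\"hypothetical protein\"",
    "ORIGIN")
  body <- vapply(seq(1, nchar(seq), by = 60), function(i)
    sprintf("%9d %s", i, tolower(substr(seq, i, min(i + 59, nchar(seq))))),
    character(1))
  c(blocks, body, "//")
}

test_that("FASTA ingest uppercases, applies sidecar taxonomy, rejects bad codes", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chrA some description", tolower(rand_seq(1000, 3))), fa)
  tax <- data.frame(chromosome = "chrA", organism = "Testus exemplaris",
                    phylum = "Proteobacteria", class = "Gamma",
                    genus = "Testus", stringsAsFactors = FALSE)
  g <- read_genomes(fa, annotation_table = tax)
  expect_length(g, 1)
  expect_identical(g[["chrA"]]$id, "chrA")
  expect_false(grepl("[a-z]", g[["chrA"]]$sequence))
  expect_identical(g[["chrA"]]$taxonomy$genus, "Testus")
  expect_identical(nrow(g[["chrA"]]$annotations), 0L)

  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">chrB", "ACGTRYACGT"), fa2)  # IUPAC R/Y not allowed
  expect_error(read_genomes(fa2), "disallowed characters")
})

test_that("GenBank ingest maps CDS features and rejects linear records", {
  seq <- rand_seq(1000, 12)
  gb <- tempfile(fileext = ".gb")
  writeLines(genbank_fixture(seq), gb)
  g <- read_genomes(gb)
  ch <- g[[1]]
  expect_identical(ch$organism, "Testus exemplaris")
  expect_identical(ch$sequence, seq)
  xer <- ch$annotations[ch$annotations$symbol == "xerC", ]
  expect_identical(nrow(xer), 1L)
  expect_identical(xer$start, 51L)
  expect_identical(xer$end, 950L)
  expect_identical(xer$strand, "+")
  expect_identical(xer$protein, "MKTWLERFLT")
  expect_identical(ch$annotations$strand[ch$annotations$symbol == "other"], "-")

  gbl <- tempfile(fileext = ".gb")
  writeLines(genbank_fixture(seq, topology = "linear"), gbl)
  expect_error(read_genomes(gbl), "linear")
})

test_that("duplicate chromosome ids are a conflict", {
  fa1 <- tempfile(fileext = ".fasta"); fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", rand_seq(100, 1)), fa1)
  writeLines(c(">dup", rand_seq(100, 2)), fa2)
  expect_error(read_genomes(c(fa1, fa2)), "duplicate")
})

test_that("FASTA round-trip preserves sequence content exactly", {
  seq <- rand_seq(5000, 13)
  fa <- tempfile(fileext = ".fasta")
  set <- Biostrings::DNAStringSet(seq); names(set) <- "rt"
  Biostrings::writeXStringSet(set, fa, width = 60)
  expect_identical(read_genomes(fa)[["rt"]]$sequence, seq)
})

make_pred_row <- function(chrom = "c1", start = 500L) {
  data.frame(organism = "org", chromosome = chrom, start = start,
             strand = "+", sequence = strrep("A", 28), score = 25.5,
             evalue = 1e-8, palindrome_pairs = 6L, check_score = TRUE,
             check_evalue = TRUE, check_palindrome = TRUE,
             check_position = TRUE, status = "validated",
             method = "profile", note = "", stringsAsFactors = FALSE)
}

make_skew_row <- function(chrom = "c1") {
  data.frame(chromosome = chrom, length = 10000L, ori = 1L, ter = 5000L,
             gcsi = 0.2, skew_visible = TRUE, stringsAsFactors = FALSE)
}

test_that("report writer uses the BED/GFF coordinate conventions", {
  out <- tempfile()
  write_report(make_pred_row(), make_skew_row(), out)
  bed <- read.delim(file.path(out, "sites.bed"), header = FALSE)
  expect_identical(bed$V2, 499L)
  expect_identical(bed$V3, 527L)
  gff <- readLines(file.path(out, "sites.gff3"))
  fields <- strsplit(gff[2], "\t")[[1]]
  expect_identical(as.integer(fields[4]), bed$V2 + 1L)  # GFF.start = BED.start+1
  expect_identical(as.integer(fields[5]), bed$V3)       # GFF.end = BED.end
})

test_that("empty prediction set yields a header-only TSV", {
  out <- tempfile()
  write_report(make_pred_row()[0, ], make_skew_row(), out)
  lines <- readLines(file.path(out, "predictions.tsv"))
  expect_length(lines, 1)
  expect_match(lines[1], "^organism\tchromosome")
})

test_that("predictions TSV round-trips byte-identically", {
  out <- tempfile()
  preds <- rbind(make_pred_row("c1", 500L), {
    r <- make_pred_row("c2", 9973L); r$status <- "provisional"
    r$score <- 8.12345; r$evalue <- 0.00321; r
  })
  skews <- rbind(make_skew_row("c1"), make_skew_row("c2"))
  write_report(preds, skews, out)
  path <- file.path(out, "predictions.tsv")
  again <- file.path(out, "again.tsv")
  write.table(read_predictions(path), again, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  expect_identical(readLines(path), readLines(again))
})

test_that("unknown chromosome id in predictions is a consistency error", {
  expect_error(write_report(make_pred_row("ghost"), make_skew_row(),
                            tempfile()),
               "unknown chromosome")
})
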