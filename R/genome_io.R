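#' Read chromosomes from FASTA or GenBank files
#'
#' FASTA records take their id from the first header token and are assumed
#' circular (the pipeline only operates on circular chromosomes); GenBank
#' records carry topology on the LOCUS line and linear records are rejected.
#' GenBank CDS features whose \code{/gene} or \code{/product} qualifier
#' matches xerC/xerD/ftsK populate the annotation table, including their
#' \code{/translation}.
#'
#' @param paths character vector of FASTA/GenBank file paths.
#' @param annotation_table optional TSV path (or data frame) supplying
#'   taxonomy and XerC/XerD proteins when the source file has none. Columns:
#'   \code{chromosome}, \code{organism}, \code{phylum}, \code{class},
#'   \code{genus}, and optionally \code{symbol}, \code{start}, \code{end},
#'   \code{strand}, \code{protein} (one row per gene; rows with empty
#'   \code{symbol} carry taxonomy only).
#' @return list of \code{\link{chromosome}} objects, named by id.
#' @export
read_genomes <- function(paths, annotation_table = NULL) {
  ann <- read_annotation_table(annotation_table)
  out <- list()
  for (path in paths) {
    if (!file.exists(path)) stopf("input file not found: %s", path)
    first <- readLines(path, n = 1L, warn = FALSE)
    chroms <- if (startsWith(first, ">")) {
      read_fasta_chromosomes(path)
    } else if (startsWith(first, "LOCUS")) {
      list(read_genbank_chromosome(path))
    } else {
      stopf("unrecognized format (neither FASTA nor GenBank): %s", path)
    }
    for (ch in chroms) {
      if (ch$id %in% names(out))
        stopf("duplicate chromosome id '%s' (second occurrence in %s)",
              ch$id, path)
      out[[ch$id]] <- ch
    }
  }
  if (!is.null(ann)) out <- lapply(out, apply_annotation_table, ann = ann)
  out
}

read_fasta_chromosomes <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stopf("unparseable FASTA: %s", path))
  lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    chromosome(id, as.character(set[[i]]))
  })
}

# Minimal GenBank flat-file reader: LOCUS topology, ORGANISM, CDS features
# (gene/product/translation), ORIGIN sequence. No installed R package parses
# local GenBank flat files, hence this purpose-built reader.
read_genbank_chromosome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- lines[startsWith(lines, "LOCUS")]
  if (!length(locus)) stopf("unparseable GenBank (no LOCUS line): %s", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  if (topology == "linear")
    stopf("chromosome '%s' in %s is linear; only circular chromosomes are supported",
          id, path)

  organism <- id
  oi <- grep("^\\s{2}ORGANISM", lines)
  if (length(oi)) organism <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[oi[1]]))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stopf("unparseable GenBank (no ORIGIN): %s", path)
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  ann <- empty_annotations()
  if (length(fstart)) {
    feat_lines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    ann <- parse_genbank_cds(feat_lines)
  }
  chromosome(id, sequence, organism = organism, topology = "circular",
             annotations = ann)
}

parse_genbank_cds <- function(feat_lines) {
  # split feature table into blocks starting at a feature key
  key_idx <- grep("^\\s{5}\\S", feat_lines)
  ann <- empty_annotations()
  if (!length(key_idx)) return(ann)
  bounds <- c(key_idx, length(feat_lines) + 1L)
  for (k in seq_along(key_idx)) {
    block <- feat_lines[bounds[k]:(bounds[k + 1L] - 1L)]
    head <- strsplit(trimws(block[1]), "\\s+")[[1]]
    if (head[1] != "CDS") next
    loc <- head[2]
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) next
    body <- paste(trimws(block[-1]), collapse = " ")
    qual <- function(name) {
      m <- regmatches(body, regexec(sprintf('/%s="([^"]*)"', name), body))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    gene <- qual("gene"); product <- qual("product")
    sym <- classify_gene_symbol(gene, product)
    protein <- qual("translation")
    if (!is.na(protein)) protein <- gsub(" ", "", protein)
    ann <- rbind(ann, data.frame(
      symbol = sym, start = nums[1], end = nums[2], strand = strand,
      protein = if (is.na(protein)) NA_character_ else protein,
      stringsAsFactors = FALSE))
  }
  ann
}

classify_gene_symbol <- function(gene, product) {
  text <- tolower(paste(gene, product))
  if (grepl("xerc", text)) "xerC"
  else if (grepl("xerd", text)) "xerD"
  else if (grepl("ftsk", text)) "ftsK"
  else "other"
}

read_annotation_table <- function(annotation_table) {
  if (is.null(annotation_table)) return(NULL)
  ann <- if (is.data.frame(annotation_table)) annotation_table
         else read.delim(annotation_table, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("chromosome", "organism", "phylum", "class", "genus")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stopf("annotation table lacks required columns: %s",
          paste(miss, collapse = ", "))
  for (col in c("symbol", "start", "end", "strand", "protein"))
    if (is.null(ann[[col]])) ann[[col]] <- NA_character_
  ann
}

apply_annotation_table <- function(chrom, ann) {
  rows <- ann[ann$chromosome == chrom$id, , drop = FALSE]
  if (!nrow(rows)) return(chrom)
  first <- rows[1, ]
  genes <- rows[!is.na(rows$symbol) & nzchar(rows$symbol) &
                  rows$symbol != ".", , drop = FALSE]
  gann <- if (nrow(genes)) {
    data.frame(symbol = genes$symbol,
               start = as.integer(genes$start),
               end = as.integer(genes$end),
               strand = genes$strand,
               protein = genes$protein,
               stringsAsFactors = FALSE)
  } else empty_annotations()
  chromosome(chrom$id, chrom$sequence,
             organism = first$organism,
             phylum = first$phylum, class = first$class, genus = first$genus,
             topology = chrom$topology,
             annotations = rbind(chrom$annotations, gann))
}

#' Write prediction and replication-statistics reports
#'
#' Emits \code{predictions.tsv} (one row per chromosome), \code{sites.bed}
#' (BED6, half-open 0-based) and \code{sites.gff3} (1-based inclusive) for
#' located sites, and \code{summary.json} with run totals. BED and GFF3
#' describe the identical interval under their conventions
#' (\code{BED.start = GFF.start - 1}, \code{BED.end = GFF.end}).
#'
#' @param predictions prediction data frame as produced by
#'   \code{\link{run_phylum}} (component \code{predictions}).
#' @param skews skew-report data frame from \code{\link{skew_report_table}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(predictions, skews, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unknown <- setdiff(predictions$chromosome, skews$chromosome)
  if (length(unknown))
    stopf("predictions reference unknown chromosome id(s): %s",
          paste(unknown, collapse = ", "))

  m <- merge(predictions, skews, by = "chromosome", all.x = TRUE, sort = FALSE)
  m <- m[order(m$chromosome), , drop = FALSE]
  dif_rel <- ifelse(!is.na(m$start) & m$skew_visible,
                    replichore_relative(m$start, m$ori, m$length), NA_real_)
  tsv <- data.frame(
    organism = m$organism, chromosome = m$chromosome,
    dif_start = ifelse(is.na(m$start), "NA", as.character(m$start)),
    strand = ifelse(is.na(m$strand), "NA", m$strand),
    dif_sequence = ifelse(is.na(m$sequence), "NA", m$sequence),
    score = fmt_num(m$score), evalue = fmt_num(m$evalue, 4),
    palindrome_pairs = ifelse(is.na(m$palindrome_pairs), "NA",
                              as.character(m$palindrome_pairs)),
    status = m$status, method = m$method,
    ori = as.character(m$ori), ter = as.character(m$ter),
    gcsi = fmt_num(m$gcsi, 4), dif_replichore_pct = fmt_num(dif_rel, 4),
    stringsAsFactors = FALSE)
  tsv_path <- file.path(out_dir, "predictions.tsv")
  write_tsv_plain(tsv, tsv_path)

  sited <- m[!is.na(m$start), , drop = FALSE]
  bed_path <- file.path(out_dir, "sites.bed")
  gff_path <- file.path(out_dir, "sites.gff3")
  bed_lines <- if (nrow(sited)) {
    sprintf("%s\t%d\t%d\tdif_%s\t%s\t%s", sited$chromosome,
            sited$start - 1L, sited$start + 27L, sited$chromosome,
            fmt_num(sited$score), sited$strand)
  } else character()
  writeLines(bed_lines, bed_path)
  gff_lines <- c("##gff-version 3",
    if (nrow(sited) > 0) sprintf(
      "%s\tdifscan\tsequence_feature\t%d\t%d\t%s\t%s\t.\tID=dif_%s;status=%s;method=%s",
      sited$chromosome, sited$start, sited$start + 27L, fmt_num(sited$score),
      sited$strand, sited$chromosome, sited$status, sited$method))
  writeLines(gff_lines, gff_path)

  summary <- list(
    n_chromosomes = nrow(m),
    n_validated = sum(m$status == "validated"),
    n_provisional = sum(m$status == "provisional"),
    n_ambiguous = sum(m$status == "ambiguous"),
    n_failed = sum(m$status == "failed"),
    n_skew_visible = sum(skews$skew_visible))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(c(tsv = tsv_path, bed = bed_path, gff = gff_path,
              summary = json_path))
}

#' Re-read a predictions TSV written by \code{\link{write_report}}
#'
#' All columns are returned as character so that writing the table again
#' reproduces the file byte-identically.
#'
#' @param path path to \code{predictions.tsv}.
#' @return data frame of character columns.
#' @export
read_predictions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
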