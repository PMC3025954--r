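#' Specification of a synthetic clade study
#'
#' Defines the study conditions for the ground-truth simulator: a star
#' phylogeny over genera (the genus-g ancestor sits g branch-units from the
#' root, leaves one unit below their ancestor, giving the decreasing-
#' similarity gradient the iterated search exploits), two-replichore genomes
#' with tunable compositional skew, one implanted dif per chromosome near
#' the terminus, and XerC/XerD proteins co-diverging with the tree.
#'
#' @param n_genera number of genera (default 6).
#' @param genomes_per_genus leaves per genus (default 5).
#' @param genome_length chromosome length in bases (default 100000,
#'   minimum 10000).
#' @param gc_content genome GC fraction (default 0.5).
#' @param skew_strength leading-strand excess (P(G) - P(C)) /
#'   \code{gc_content}, in [0, 1] (default 0.25, a visible-to-pronounced
#'   skew on the GCSI scale).
#' @param motif_sub_rate dif substitutions/site/branch-unit (default 0.03).
#' @param protein_sub_rate protein substitutions/site/branch-unit
#'   (default 0.04).
#' @param xerD_arm_rate_factor multiplier (<= 1) on the motif rate at
#'   positions 13-28, emulating the stronger conservation of the XerD arm
#'   (default 0.5).
#' @param pair_compensation probability that a substitution breaking one of
#'   the six checked arm pairs is accompanied by a complement-restoring
#'   substitution at the partner position (purifying selection on arm
#'   complementarity; default 0.8).
#' @param replichore_asymmetry half-width of the uniform terminus offset
#'   from the origin antipode, as a fraction of genome length (default
#'   0.12): replichores are realistically unequal, which spreads the
#'   terminus over a range of replichore-relative positions.
#' @param implant_jitter half-width of the uniform implant offset from the
#'   true terminus, as a fraction of genome length (default 0.02).
#' @param negative_fraction fraction of genomes left without an implant as
#'   negative controls (default 0; the seed organism is never a control).
#' @param root_dif ancestral 28-mer (default: the E. coli seed).
#' @param protein_length length of the simulated recombinase proteins
#'   (default 298).
#' @param random_seed integer seed; the whole study is deterministic
#'   given it.
#' @return object of class \code{clade_spec}.
#' @export
clade_spec <- function(n_genera = 6, genomes_per_genus = 5,
                       genome_length = 100000, gc_content = 0.5,
                       skew_strength = 0.25, motif_sub_rate = 0.03,
                       protein_sub_rate = 0.04, xerD_arm_rate_factor = 0.5,
                       pair_compensation = 0.8, replichore_asymmetry = 0.12,
                       implant_jitter = 0.02, negative_fraction = 0,
                       root_dif = published_seeds()$e_coli$sequence,
                       protein_length = 298, random_seed = 1) {
  if (genome_length < 10000) stopf("genome_length must be >= 10000")
  for (r in c(motif_sub_rate, protein_sub_rate))
    if (r < 0 || r > 1) stopf("substitution rates must be in [0, 1]")
  if (xerD_arm_rate_factor > 1 || xerD_arm_rate_factor < 0)
    stopf("xerD_arm_rate_factor must be in [0, 1]")
  if (nchar(root_dif) != 28) stopf("root_dif must be a 28-mer")
  structure(as.list(environment()), class = "clade_spec")
}

#' Generate a circular genome with two-replichore GC skew
#'
#' Bases are i.i.d. within each replichore. On the leading replichore
#' (origin to terminus along the forward strand) P(G) - P(C) =
#' \code{skew_strength} x \code{gc}; the bias is reversed on the other
#' replichore; A and T are balanced.
#'
#' @param length genome length.
#' @param gc GC fraction.
#' @param skew_strength skew strength in [0, 1].
#' @param ori origin position (default 1).
#' @param ter terminus position (default: antipode of \code{ori}).
#' @param seed integer RNG seed.
#' @param id,organism identifiers for the returned chromosome.
#' @return a circular \code{\link{chromosome}}.
#' @export
generate_skewed_genome <- function(length, gc = 0.5, skew_strength = 0.25,
                                   ori = 1, ter = NULL, seed = 1,
                                   id = "synthetic", organism = id) {
  if (gc <= 0 || gc >= 1) stopf("gc must be in (0, 1)")
  if (skew_strength < 0 || skew_strength > 1)
    stopf("skew_strength must be in [0, 1] (probabilities would be negative)")
  if (is.null(ter)) ter <- wrap_pos(ori + length / 2, length)
  ori <- wrap_pos(round(ori), length); ter <- wrap_pos(round(ter), length)
  pG_lead <- gc * (1 + skew_strength) / 2
  pC_lead <- gc * (1 - skew_strength) / 2
  pAT <- (1 - gc) / 2
  p_lead <- c(pAT, pC_lead, pG_lead, pAT)   # A C G T
  p_lag <- c(pAT, pG_lead, pC_lead, pAT)
  with_seed(seed, {
    # leading replichore: positions ori..ter-1 walking forward (wrapping)
    lead_len <- (ter - ori) %% length
    if (lead_len == 0) lead_len <- length %/% 2
    bases <- character(length)
    lead_idx <- wrap_pos(seq.int(ori, ori + lead_len - 1), length)
    lag_idx <- setdiff(seq_len(length), lead_idx)
    bases[lead_idx] <- sample(DNA_BASES, lead_len, replace = TRUE,
                              prob = p_lead)
    bases[lag_idx] <- sample(DNA_BASES, length(lag_idx), replace = TRUE,
                             prob = p_lag)
    chromosome(id, paste(bases, collapse = ""), organism = organism)
  })
}

# checked arm pairs (i, 29-i) for i in 7..12
PAIR_POS <- cbind(7:12, 22:17)

mutate_motif <- function(motif, branch_len, rate, arm_factor,
                         pair_compensation) {
  b <- strsplit(motif, "", fixed = TRUE)[[1]]
  before <- b
  site_rate <- rep(rate, 28)
  site_rate[13:28] <- site_rate[13:28] * arm_factor
  p_sub <- 1 - exp(-site_rate * branch_len)
  hit <- runif(28) < p_sub
  for (i in which(hit))
    b[i] <- sample(setdiff(DNA_BASES, b[i]), 1)
  # purifying selection on arm complementarity: a broken checked pair is
  # restored by a compensatory substitution at the partner position
  for (k in seq_len(nrow(PAIR_POS))) {
    i <- PAIR_POS[k, 1]; j <- PAIR_POS[k, 2]
    was_paired <- before[j] == complement_base(before[i])
    is_paired <- b[j] == complement_base(b[i])
    if (was_paired && !is_paired && runif(1) < pair_compensation)
      b[j] <- complement_base(b[i])
  }
  paste(b, collapse = "")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_protein <- function(protein, branch_len, rate) {
  a <- strsplit(protein, "", fixed = TRUE)[[1]]
  p_sub <- 1 - exp(-rate * branch_len)
  hit <- runif(length(a)) < p_sub
  for (i in which(hit))
    a[i] <- sample(setdiff(AA_ALPHABET, a[i]), 1)
  paste(a, collapse = "")
}

#' Evolve a synthetic clade with implanted dif sites
#'
#' Walks the star phylogeny of a \code{\link{clade_spec}}: along each branch
#' the dif 28-mer accrues substitutions at \code{motif_sub_rate} (positions
#' 13-28 scaled by \code{xerD_arm_rate_factor}, checked arm pairs protected
#' by compensatory substitutions with probability \code{pair_compensation})
#' and the XerC/XerD proteins at \code{protein_sub_rate}. Each leaf receives
#' a skewed genome with one implant near its terminus (negative-control
#' leaves receive none) plus xerC/xerD gene annotations carrying the evolved
#' proteins.
#'
#' @param spec a \code{\link{clade_spec}}.
#' @return list with \code{genomes} (list of \code{\link{chromosome}}),
#'   \code{truth} (data frame: chromosome, organism, genus, class,
#'   implanted, implant_start, implant_strand, implant_seq, true_ori,
#'   true_ter, tree_depth), and \code{seed} (the study's
#'   \code{\link{seed_dif}}: the seed organism's own implanted site).
#' @export
evolve_clade <- function(spec) {
  stopifnot(inherits(spec, "clade_spec"))
  max_depth <- spec$n_genera + 1
  if (1 - exp(-spec$motif_sub_rate * max_depth) > 0.5)
    warnf("motif substitution rate implies < 50%% expected identity at the deepest leaves; method assumptions violated")

  with_seed(spec$random_seed, {
    root_xerC <- paste(sample(AA_ALPHABET, spec$protein_length,
                              replace = TRUE), collapse = "")
    root_xerD <- paste(sample(AA_ALPHABET, spec$protein_length,
                              replace = TRUE), collapse = "")

    n_leaves <- spec$n_genera * spec$genomes_per_genus
    leaf_names <- character(n_leaves)
    k <- 0
    leaves <- list()
    for (g in seq_len(spec$n_genera)) {
      genus <- sprintf("Genus_%02d", g)
      cls <- sprintf("Class_%s", LETTERS[ceiling(g / 3)])
      # genus ancestor: g branch-units below the root
      anc_dif <- mutate_motif(spec$root_dif, g, spec$motif_sub_rate,
                              spec$xerD_arm_rate_factor,
                              spec$pair_compensation)
      anc_xerC <- mutate_protein(root_xerC, g, spec$protein_sub_rate)
      anc_xerD <- mutate_protein(root_xerD, g, spec$protein_sub_rate)
      for (i in seq_len(spec$genomes_per_genus)) {
        k <- k + 1
        leaves[[k]] <- list(
          genus = genus, class = cls,
          organism = sprintf("%s sp. %d", genus, i),
          id = sprintf("chr_%02d_%02d", g, i),
          depth = g + 1,
          dif = mutate_motif(anc_dif, 1, spec$motif_sub_rate,
                             spec$xerD_arm_rate_factor,
                             spec$pair_compensation),
          xerC = mutate_protein(anc_xerC, 1, spec$protein_sub_rate),
          xerD = mutate_protein(anc_xerD, 1, spec$protein_sub_rate))
      }
    }

    # negative controls: drawn over all leaves except the seed organism
    n_neg <- round(spec$negative_fraction * n_leaves)
    neg_idx <- if (n_neg > 0) sample(2:n_leaves, n_neg) else integer()

    L <- spec$genome_length
    genomes <- vector("list", n_leaves)
    truth <- vector("list", n_leaves)
    for (k in seq_len(n_leaves)) {
      lf <- leaves[[k]]
      ori <- sample.int(L, 1)
      ter <- wrap_pos(ori + L / 2 +
                        round(runif(1, -1, 1) * spec$replichore_asymmetry * L),
                      L)
      gseed <- derive_seed(spec$random_seed, k)
      ch <- generate_skewed_genome(L, spec$gc_content, spec$skew_strength,
                                   ori = ori, ter = ter, seed = gseed,
                                   id = lf$id, organism = lf$organism)
      implanted <- !(k %in% neg_idx)
      implant_start <- NA_integer_; implant_strand <- NA_character_
      implant_seq <- NA_character_
      if (implanted) {
        implant_start <- wrap_pos(
          ter + round(runif(1, -1, 1) * spec$implant_jitter * L), L)
        implant_strand <- sample(c("+", "-"), 1)
        implant_seq <- lf$dif
        ch <- implant_site(ch, implant_seq, implant_start, implant_strand)
      }
      ann <- xer_annotations(lf, implant_start, ori, L)
      genomes[[k]] <- chromosome(lf$id, ch$sequence, organism = lf$organism,
                                 phylum = "Synthophyla", class = lf$class,
                                 genus = lf$genus, annotations = ann)
      truth[[k]] <- data.frame(
        chromosome = lf$id, organism = lf$organism, genus = lf$genus,
        class = lf$class, implanted = implanted,
        implant_start = implant_start, implant_strand = implant_strand,
        implant_seq = implant_seq, true_ori = ori, true_ter = ter,
        tree_depth = lf$depth, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    names(genomes) <- truth$chromosome
    seed <- seed_dif(truth$organism[1], truth$implant_seq[1],
                     "experimental")
    list(genomes = genomes, truth = truth, seed = seed)
  })
}

# overwrite 28 bases at start (wrapping) with the motif on the given strand
implant_site <- function(chrom, motif, start, strand) {
  written <- if (strand == "-") reverse_complement(motif) else motif
  b <- strsplit(chrom$sequence, "", fixed = TRUE)[[1]]
  idx <- wrap_pos(seq.int(start, start + 27L), chrom$length)
  b[idx] <- strsplit(written, "", fixed = TRUE)[[1]]
  chromosome(chrom$id, paste(b, collapse = ""), organism = chrom$organism,
             phylum = chrom$taxonomy$phylum, class = chrom$taxonomy$class,
             genus = chrom$taxonomy$genus, annotations = chrom$annotations)
}

# xerC near the dif site, xerD near the origin (positions are cosmetic
# context; the proteins are what the pipeline consumes)
xer_annotations <- function(leaf, implant_start, ori, L) {
  anchorC <- if (is.na(implant_start)) wrap_pos(ori + L / 4, L) else implant_start
  # keep synthesized genes clear of the sequence origin: no wrap-around
  # features are ever generated (wrap-around is accepted on ingest only)
  s1 <- min(wrap_pos(anchorC - 2000, L), L - 897)
  s2 <- min(wrap_pos(ori + 3000, L), L - 897)
  data.frame(
    symbol = c("xerC", "xerD"),
    start = c(s1, s2),
    end = c(s1 + 897, s2 + 897),
    strand = c("+", "+"),
    protein = c(leaf$xerC, leaf$xerD),
    stringsAsFactors = FALSE)
}

#' Write a synthetic study bundle to disk
#'
#' Materializes \code{\link{evolve_clade}} output as a directory the
#' pipeline can ingest with no special casing: \code{genomes/*.fasta},
#' \code{annotations.tsv} (taxonomy + XerC/XerD proteins),
#' \code{seeds.fasta}, \code{truth.tsv} and \code{config.yaml}.
#'
#' @param spec a \code{\link{clade_spec}} (or path to a YAML file of
#'   \code{clade_spec} arguments).
#' @param out_dir output directory.
#' @param overwrite overwrite an existing bundle (default FALSE).
#' @return invisibly, a list with \code{dir}, \code{genome_paths},
#'   \code{annotation_path}, \code{seed_path}, \code{truth_path} and the
#'   in-memory \code{study}.
#' @export
make_study <- function(spec = clade_spec(), out_dir, overwrite = FALSE) {
  if (is.character(spec)) {
    args <- yaml::read_yaml(spec)
    spec <- do.call(clade_spec, args)
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stopf("output directory %s exists; use overwrite = TRUE", out_dir)
  dir.create(file.path(out_dir, "genomes"), showWarnings = FALSE,
             recursive = TRUE)
  study <- evolve_clade(spec)

  genome_paths <- character(length(study$genomes))
  for (i in seq_along(study$genomes)) {
    ch <- study$genomes[[i]]
    set <- Biostrings::DNAStringSet(ch$sequence)
    names(set) <- ch$id
    genome_paths[i] <- file.path(out_dir, "genomes",
                                 paste0(ch$id, ".fasta"))
    Biostrings::writeXStringSet(set, genome_paths[i], width = 70)
  }

  ann <- do.call(rbind, lapply(study$genomes, function(ch) {
    a <- ch$annotations
    data.frame(chromosome = ch$id, organism = ch$organism,
               phylum = ch$taxonomy$phylum, class = ch$taxonomy$class,
               genus = ch$taxonomy$genus,
               symbol = a$symbol, start = a$start, end = a$end,
               strand = a$strand, protein = a$protein,
               stringsAsFactors = FALSE)
  }))
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_tsv_plain(ann, ann_path)

  seed_path <- file.path(out_dir, "seeds.fasta")
  writeLines(c(paste0(">", study$seed$organism), study$seed$sequence),
             seed_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv_plain(study$truth, truth_path)

  cfg <- unclass(spec)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  invisible(list(dir = out_dir, genome_paths = genome_paths,
                 annotation_path = ann_path, seed_path = seed_path,
                 truth_path = truth_path, study = study))
}
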