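#' Pairwise protein identity distance
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring and affine gaps
#' (open 10, extend 0.5); distance is one minus the fraction of identical
#' residue pairs over aligned columns (gap-gap columns cannot occur in a
#' pairwise global alignment). Symmetric, zero on identity, in [0, 1].
#'
#' @param a,b amino-acid strings (non-empty).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return distance in \code{[0, 1]}.
#' @examples
#' protein_distance("AAAA", "AAAC")  # 0.25
#' @export
protein_distance <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b))
    stopf("protein_distance: sequences must be non-empty")
  if (a == b) return(0)
  # canonical argument order: alignment tie-breaking is not symmetric, the
  # distance must be
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- !(p == "-" & s == "-")
  1 - sum(p[keep] == s[keep] & p[keep] != "-") / sum(keep)
}

blosum62_env <- new.env()
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

#' Average XerC/XerD distance matrix between organisms
#'
#' Per-pair distance is the mean of the XerC and XerD protein distances.
#' Organisms missing either protein are dropped with a warning (the method
#' only applies to XerCD-bearing genomes).
#'
#' @param genomes list of \code{\link{chromosome}} objects.
#' @return list with \code{matrix} (symmetric, organisms x organisms),
#'   \code{organisms}, and \code{excluded} (organisms without XerC or XerD).
#' @export
distance_matrix <- function(genomes) {
  orgs <- organism_table(genomes)
  has <- vapply(orgs, function(o)
    !is.na(o$proteins$xerC) && !is.na(o$proteins$xerD), logical(1))
  excluded <- names(orgs)[!has]
  if (length(excluded))
    warnf("excluding organism(s) without XerC/XerD proteins: %s",
          paste(excluded, collapse = ", "))
  orgs <- orgs[has]
  n <- length(orgs)
  m <- matrix(0, n, n, dimnames = list(names(orgs), names(orgs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dC <- protein_distance(orgs[[i]]$proteins$xerC, orgs[[j]]$proteins$xerC)
      dD <- protein_distance(orgs[[i]]$proteins$xerD, orgs[[j]]$proteins$xerD)
      m[i, j] <- m[j, i] <- (dC + dD) / 2
    }
  }
  list(matrix = m, organisms = orgs, excluded = excluded)
}

# group chromosomes into organisms, carrying taxonomy and Xer proteins
organism_table <- function(genomes) {
  orgs <- list()
  for (ch in genomes) {
    o <- ch$organism
    if (is.null(orgs[[o]])) {
      orgs[[o]] <- list(organism = o, taxonomy = ch$taxonomy,
                        chromosomes = character(), proteins = xer_proteins(ch))
    }
    orgs[[o]]$chromosomes <- c(orgs[[o]]$chromosomes, ch$id)
    # fill proteins from whichever chromosome carries them
    pr <- xer_proteins(ch)
    if (is.na(orgs[[o]]$proteins$xerC)) orgs[[o]]$proteins$xerC <- pr$xerC
    if (is.na(orgs[[o]]$proteins$xerD)) orgs[[o]]$proteins$xerD <- pr$xerD
  }
  orgs
}

#' Iteration order for recursive profile training
#'
#' Organisms are grouped by genus (or class); each group's distance to the
#' seed organism is the minimum member distance (closest representative) and
#' groups are visited in ascending distance, the seed's own group first.
#' Ties break lexicographically on the group label.
#'
#' @param genomes list of \code{\link{chromosome}} objects.
#' @param seed_organism organism name of the seed.
#' @param group_by \code{"genus"} or \code{"class"}.
#' @param dmat optional precomputed \code{\link{distance_matrix}} result.
#' @return object of class \code{iteration_order}: list with
#'   \code{seed_organism} and \code{groups}, each group a list of
#'   \code{label}, \code{organisms} (ascending distance, then name) and
#'   \code{distance}.
#' @export
build_iteration_order <- function(genomes, seed_organism,
                                  group_by = c("genus", "class"),
                                  dmat = NULL) {
  group_by <- match.arg(group_by)
  if (is.null(dmat)) dmat <- distance_matrix(genomes)
  orgs <- dmat$organisms
  if (!seed_organism %in% names(orgs))
    stopf("seed organism '%s' not among usable genomes", seed_organism)
  d <- dmat$matrix[seed_organism, ]
  labels <- vapply(orgs, function(o) {
    lab <- o$taxonomy[[group_by]]
    if (is.na(lab)) "unknown" else lab
  }, character(1))
  seed_label <- labels[[seed_organism]]
  groups <- lapply(sort(unique(labels)), function(lab) {
    members <- names(labels)[labels == lab]
    members <- members[order(d[members], members)]
    list(label = lab, organisms = members, distance = min(d[members]))
  })
  ord <- order(vapply(groups, `[[`, numeric(1), "distance"),
               vapply(groups, `[[`, character(1), "label"))
  groups <- groups[ord]
  is_seed <- vapply(groups, function(g) g$label == seed_label, logical(1))
  groups <- c(groups[is_seed], groups[!is_seed])
  structure(list(seed_organism = seed_organism, group_by = group_by,
                 groups = groups),
            class = "iteration_order")
}

#' @export
print.iteration_order <- function(x, ...) {
  cat(sprintf("<iteration_order> seed=%s, grouped by %s\n",
              x$seed_organism, x$group_by))
  for (g in x$groups)
    cat(sprintf("  %-20s d=%.4f  n=%d\n", g$label, g$distance,
                length(g$organisms)))
  invisible(x)
}

#' The k trained genomes nearest to a target organism
#'
#' Selects the \code{k} organisms minimizing average XerC/XerD distance to
#' the target (simple k-smallest rule; ties break on organism name). Used to
#' build alternative seed profiles from the closest already-predicted
#' genomes.
#'
#' @param target organism name.
#' @param trained character vector of trained organism names.
#' @param dmat \code{\link{distance_matrix}} result covering all of them.
#' @param k number to select (default 3).
#' @return character vector of up to \code{k} organism names.
#' @export
nearest_training_genomes <- function(target, trained, dmat, k = 3) {
  trained <- setdiff(trained, target)
  if (length(trained) < k) {
    warnf("only %d trained genome(s) available for target '%s' (k=%d)",
          length(trained), target, k)
    k <- length(trained)
  }
  d <- dmat$matrix[target, trained]
  trained[order(d, trained)][seq_len(k)]
}
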