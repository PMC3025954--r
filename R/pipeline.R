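#' Pipeline configuration
#'
#' Collects the thresholds and switches of the iterated search. Defaults
#' are the strategy's standard constants: fuzzy matching allows
#' 0 insertions, 0 deletions and up to 8 substitutions; candidates validate
#' at bit score >= 10 and E-value < 1.0e-04; at least 4 of the 6 checked arm
#' pairs must be complementary; inter-phylum XerCD distances of >= 0.3 are
#' flagged when a profile crosses such a gap; GCSI >= 0.05 marks visible
#' skew.
#'
#' @param max_substitutions fuzzy-matching substitution budget (default 8).
#' @param score_threshold validation bit-score threshold (default 10).
#' @param evalue_threshold validation E-value threshold (default 1e-4).
#' @param palindrome_min minimum complementary arm pairs (default 4; the
#'   B. subtilis experimental seed itself scores exactly 4).
#' @param ori_exclusion_fraction candidates within this fraction of genome
#'   length of the origin are rejected by position (default 0.10).
#' @param phylum_gap_warn warn when a profile is applied across an XerCD
#'   distance at or above this (default 0.30).
#' @param group_by iteration grouping taxon, \code{"genus"} or
#'   \code{"class"}.
#' @param alternative_seed_k closest predicted genomes used for an
#'   alternative seed profile (default 3).
#' @param gcsi_threshold GC-skew visibility threshold (default 0.05).
#' @param pseudocount profile pseudocount (default 0.5).
#' @param reporting_evalue scan reporting ceiling (default 10).
#' @param random_seed seed recorded in run manifests (default 1; the
#'   pipeline itself is deterministic).
#' @return object of class \code{dif_config}.
#' @export
dif_config <- function(max_substitutions = 8, score_threshold = 10,
                       evalue_threshold = 1e-4, palindrome_min = 4,
                       ori_exclusion_fraction = 0.10, phylum_gap_warn = 0.30,
                       group_by = c("genus", "class"),
                       alternative_seed_k = 3, gcsi_threshold = 0.05,
                       pseudocount = 0.5, reporting_evalue = 10,
                       random_seed = 1) {
  group_by <- match.arg(group_by)
  stopifnot(max_substitutions >= 0, score_threshold > 0,
            evalue_threshold > 0, palindrome_min >= 0,
            ori_exclusion_fraction >= 0, alternative_seed_k >= 1,
            gcsi_threshold > 0)
  structure(as.list(environment()), class = "dif_config")
}

failed_prediction <- function(chrom, reason, method = "none") {
  data.frame(chromosome = chrom$id, start = NA_integer_,
             strand = NA_character_, sequence = NA_character_,
             score = NA_real_, evalue = NA_real_,
             palindrome_pairs = NA_integer_,
             check_score = NA, check_evalue = NA, check_palindrome = NA,
             check_position = NA,
             status = "failed", method = method, note = reason,
             stringsAsFactors = FALSE)
}

#' Bootstrap a seed profile by fuzzy matching within the seed genus
#'
#' Each genus chromosome is scanned for the seed with at most
#' \code{max_substitutions} substitutions. The best unique hit per
#' chromosome enters the training set; a chromosome with two or more
#' equally good hits is flagged ambiguous and excluded from the profile; a
#' chromosome with no hit within budget is deferred to the fallback
#' cascade.
#'
#' @param genus_genomes list of \code{\link{chromosome}} objects of the
#'   seed genus.
#' @param seed a \code{\link{seed_dif}}.
#' @param config a \code{\link{dif_config}}.
#' @return list with \code{profile} (a \code{\link{dif_profile}}),
#'   \code{training} (data frame id/sequence/chromosome/start/strand),
#'   \code{predictions} (accepted fuzzy predictions), \code{ambiguous},
#'   \code{deferred} (chromosome ids).
#' @export
bootstrap_profile <- function(genus_genomes, seed, config = dif_config()) {
  if (!length(genus_genomes)) stopf("bootstrap requires at least one genome")
  training <- list(); predictions <- list()
  ambiguous <- character(); deferred <- character()
  for (ch in genus_genomes) {
    hits <- fuzzy_scan(ch, seed, config$max_substitutions)
    if (!nrow(hits)) { deferred <- c(deferred, ch$id); next }
    best_count <- hits$substitutions[1]
    at_best <- sum(hits$substitutions == best_count)
    if (at_best > 1) {
      ambiguous <- c(ambiguous, ch$id)
      predictions[[ch$id]] <- data.frame(
        chromosome = ch$id, start = hits$start[1], strand = hits$strand[1],
        sequence = hits$matched[1], score = NA_real_, evalue = NA_real_,
        palindrome_pairs = palindrome_pairs(hits$matched[1]),
        check_score = NA, check_evalue = NA, check_palindrome = NA,
        check_position = NA, status = "ambiguous", method = "fuzzy",
        note = sprintf("%d equal-distance hits", at_best),
        stringsAsFactors = FALSE)
      next
    }
    best <- hits[1, ]
    training[[ch$id]] <- data.frame(
      id = ch$id, sequence = best$matched, chromosome = ch$id,
      start = best$start, strand = best$strand, stringsAsFactors = FALSE)
    predictions[[ch$id]] <- data.frame(
      chromosome = ch$id, start = best$start, strand = best$strand,
      sequence = best$matched, score = NA_real_, evalue = NA_real_,
      palindrome_pairs = palindrome_pairs(best$matched),
      check_score = NA, check_evalue = NA, check_palindrome = NA,
      check_position = NA, status = "validated", method = "fuzzy",
      note = sprintf("%d substitution(s)", best$substitutions),
      stringsAsFactors = FALSE)
  }
  training <- do.call(rbind, c(training, list(NULL)))
  if (is.null(training) || !nrow(training))
    stopf("bootstrap found no fuzzy hit in any genome of the seed genus")
  profile <- dif_profile(training[, c("id", "sequence")],
                         pseudocount = config$pseudocount)
  list(profile = profile, training = training,
       predictions = do.call(rbind, predictions),
       ambiguous = ambiguous, deferred = deferred)
}

# internal run state: mutable-by-return orchestration record
new_run_state <- function(profile, training, predictions, config,
                          chromosomes, skews) {
  list(profile = profile, training = training,
       predictions = predictions, config = config,
       chromosomes = chromosomes, skews = skews,
       audit = data.frame(step = character(), event = character(),
                          genome = character(), detail = character(),
                          stringsAsFactors = FALSE))
}

audit_add <- function(state, step, event, genome = "", detail = "") {
  state$audit <- rbind(state$audit, data.frame(
    step = step, event = event, genome = genome, detail = detail,
    stringsAsFactors = FALSE))
  state
}

#' Predict one taxon group and refresh the profile
#'
#' Scans each chromosome of the group with the current profile, validates
#' the best hit, appends validated sites to the training set, rebuilds the
#' profile and runs leave-one-out cross-validation. When LOOCV fails, the
#' newest additions that themselves fail are evicted (or all newest
#' additions, when only older members fail); evicted genomes keep their
#' predictions flagged not-trained-on.
#'
#' @param state run state as built inside \code{\link{run_phylum}}.
#' @param group_chromosomes list of \code{\link{chromosome}} objects.
#' @param step audit label.
#' @param method method label recorded on predictions.
#' @return updated state; component \code{unresolved} lists chromosome ids
#'   whose best hit did not validate.
#' @export
run_group_iteration <- function(state, group_chromosomes, step = "group",
                                method = "profile") {
  config <- state$config
  new_rows <- list(); unresolved <- character()
  for (ch in group_chromosomes) {
    hits <- scan_chromosome(state$profile, ch,
                            reporting_evalue = config$reporting_evalue)
    best <- hits[1, ]
    skew <- state$skews[[ch$id]]
    pred <- validate_candidate(best, skew, config, method = method)
    pred$note <- ""
    state <- audit_add(state, step, "scan", ch$id,
                       sprintf("best %d%s score %.2f E %.3g -> %s",
                               best$start, best$strand, best$bit_score,
                               best$e_value, pred$status))
    if (pred$status == "validated") {
      new_rows[[ch$id]] <- data.frame(
        id = ch$id, sequence = pred$sequence, chromosome = ch$id,
        start = pred$start, strand = pred$strand, stringsAsFactors = FALSE)
      state$predictions[[ch$id]] <- pred
    } else if (pred$status == "provisional") {
      state$predictions[[ch$id]] <- pred
    } else {
      unresolved <- c(unresolved, ch$id)
    }
  }
  new_train <- do.call(rbind, c(new_rows, list(NULL)))
  if (!is.null(new_train) && nrow(new_train)) {
    gate <- loocv_gate(rbind(state$training, new_train), new_train$id,
                       state$chromosomes, config)
    for (id in gate$evicted) {
      state <- audit_add(state, step, "loocv_evict", id,
                         "removed from training (kept as prediction)")
      state$predictions[[id]]$note <- "not-trained-on (LOOCV eviction)"
    }
    state$training <- gate$training
    state$profile <- dif_profile(state$training[, c("id", "sequence")],
                                 pseudocount = config$pseudocount)
    state <- audit_add(state, step, "profile_rebuilt", "",
                       sprintf("training size %d", nrow(state$training)))
  }
  state$unresolved <- unresolved
  state
}

#' Leave-one-out gate on an enlarged training set
#'
#' Runs \code{\link{loocv}} on the candidate training set and, while it
#' fails, evicts from the newest additions: first those that fail their own
#' held-out re-prediction, otherwise (when only older members fail) all of
#' this round's additions. Older training members are never evicted — the
#' training set only shrinks by removing the newcomers that broke it.
#'
#' @param training candidate training data frame (columns \code{id},
#'   \code{sequence}, \code{chromosome}, \code{start}, \code{strand}).
#' @param new_ids ids of this round's additions (subject to eviction).
#' @param chromosomes named list of \code{\link{chromosome}} objects.
#' @param config a \code{\link{dif_config}}.
#' @return list with \code{training} (gated set), \code{evicted} (ids) and
#'   \code{pass} (final LOOCV outcome).
#' @export
loocv_gate <- function(training, new_ids, chromosomes,
                       config = dif_config()) {
  evicted <- character()
  repeat {
    cv <- loocv(training, chromosomes,
                score_threshold = config$score_threshold,
                evalue_threshold = config$evalue_threshold,
                pseudocount = config$pseudocount)
    if (isTRUE(cv$pass) || is.na(cv$pass)) break
    failing <- cv$results$id[!cv$results$pass]
    newest <- intersect(failing, new_ids)
    evict <- if (length(newest)) newest else intersect(new_ids, training$id)
    if (!length(evict)) break  # nothing left to evict; keep the old core
    evicted <- c(evicted, evict)
    training <- training[!training$id %in% evict, , drop = FALSE]
    if (!any(training$id %in% new_ids)) {
      cv <- loocv(training, chromosomes,
                  score_threshold = config$score_threshold,
                  evalue_threshold = config$evalue_threshold,
                  pseudocount = config$pseudocount)
      break
    }
  }
  list(training = training, evicted = evicted, pass = cv$pass)
}

#' Cross-group prediction with foreign profiles
#'
#' Used when a genome cannot be reached from its own clade's seed: each
#' foreign profile scans the chromosome, and a candidate is accepted when at
#' least two profiles rank the identical site (position, strand and
#' sequence) best and it passes validation, or when a single profile's best
#' hit passes with fully validated status. When no profile clears the
#' thresholds but one site still passes the palindrome and position checks,
#' the candidate is reported provisional.
#'
#' @param genome a \code{\link{chromosome}}.
#' @param profiles named list of foreign \code{\link{dif_profile}} objects.
#' @param skew \code{\link{skew_report}} for the chromosome.
#' @param config a \code{\link{dif_config}}.
#' @return a \code{dif_prediction} row (with \code{note} recording profile
#'   provenance), or \code{NULL} when the profiles disagree and none
#'   validates.
#' @export
cross_group_predict <- function(genome, profiles, skew,
                                config = dif_config()) {
  if (!length(profiles)) return(NULL)
  best <- lapply(profiles, function(p) {
    scan_chromosome(p, genome, reporting_evalue = config$reporting_evalue)[1, ]
  })
  keys <- vapply(best, function(b)
    paste(b$start, b$strand, b$window), character(1))
  tab <- table(keys)
  agree <- names(tab)[tab >= 2]
  if (length(agree)) {
    agree <- agree[which.max(tab[agree])]
    members <- names(best)[keys == agree]
    # validate with the best-scoring agreeing profile
    scores <- vapply(best[members], `[[`, numeric(1), "bit_score")
    pick <- members[which.max(scores)]
    pred <- validate_candidate(best[[pick]], skew, config,
                               method = "cross_group")
    if (pred$status %in% c("validated", "provisional")) {
      pred$note <- sprintf("profiles agree: %s",
                           paste(sort(members), collapse = "+"))
      return(pred)
    }
  }
  # single-profile full validation
  preds <- lapply(names(best), function(nm)
    validate_candidate(best[[nm]], skew, config, method = "cross_group"))
  names(preds) <- names(best)
  ok <- names(preds)[vapply(preds, function(p) p$status == "validated",
                            logical(1))]
  if (length(ok)) {
    scores <- vapply(preds[ok], `[[`, numeric(1), "score")
    pick <- ok[which.max(scores)]
    pred <- preds[[pick]]
    pred$note <- sprintf("single profile: %s", pick)
    return(pred)
  }
  prov <- names(preds)[vapply(preds, function(p) p$status == "provisional",
                              logical(1))]
  if (length(prov)) {
    scores <- vapply(preds[prov], `[[`, numeric(1), "score")
    pick <- prov[which.max(scores)]
    pred <- preds[[pick]]
    pred$note <- sprintf("provisional via profile: %s", pick)
    return(pred)
  }
  NULL
}

#' Run the full iterated prediction for one clade
#'
#' Orchestrates the whole strategy: fuzzy-matching bootstrap in the seed
#' genus, profile iteration over taxon groups in decreasing XerCD
#' similarity with LOOCV gating, then a fallback cascade for unresolved
#' genomes — (1) a class-level pass, (2) an alternative seed profile from
#' the closest predicted genomes, (3) cross-group prediction with foreign
#' profiles (agreement of two profiles on an identical site, or one fully
#' validated), (4) a relaxed pass reporting provisional candidates. Every
#' chromosome ends in exactly one of: validated, provisional, ambiguous,
#' failed.
#'
#' @param genomes list of \code{\link{chromosome}} objects (one clade).
#' @param seed a \code{\link{seed_dif}} whose organism is among
#'   \code{genomes} (or set \code{seed_organism}).
#' @param config a \code{\link{dif_config}}.
#' @param seed_organism organism anchoring the bootstrap genus (default:
#'   \code{seed$organism}).
#' @param foreign_profiles named list of final profiles from other clades
#'   for the cross-group fallback.
#' @return object of class \code{dif_run}: list with \code{predictions}
#'   (one row per chromosome, with \code{organism}), \code{profile} (final),
#'   \code{training}, \code{skews} (data frame), \code{order},
#'   \code{audit}, \code{config}.
#' @export
run_phylum <- function(genomes, seed, config = dif_config(),
                       seed_organism = NULL,
                       foreign_profiles = list()) {
  if (!length(genomes))
    return(structure(list(predictions = empty_predictions(),
                          profile = NULL, training = NULL, skews = NULL,
                          order = NULL,
                          audit = data.frame(), config = config),
                     class = "dif_run"))
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  if (is.null(seed_organism)) seed_organism <- seed$organism
  org_of <- vapply(genomes, `[[`, character(1), "organism")

  skews <- lapply(genomes, skew_report,
                  gcsi_threshold = config$gcsi_threshold)
  names(skews) <- names(genomes)

  dmat <- suppressWarnings(distance_matrix(genomes))
  usable_orgs <- rownames(dmat$matrix)
  no_xer <- setdiff(unique(org_of), usable_orgs)

  seed_genome <- genomes[org_of == seed_organism]
  if (!length(seed_genome))
    stopf("seed organism '%s' not among the input genomes", seed_organism)
  seed_genus <- seed_genome[[1]]$taxonomy$genus

  genus_ids <- names(genomes)[vapply(genomes, function(g)
    identical(g$taxonomy$genus, seed_genus), logical(1))]
  boot <- bootstrap_profile(genomes[genus_ids], seed, config)
  predictions <- split(boot$predictions, boot$predictions$chromosome)
  state <- new_run_state(boot$profile, boot$training, predictions, config,
                         genomes, skews)
  state <- audit_add(state, "bootstrap", "profile_built", "",
                     sprintf("genus %s: %d trained, %d ambiguous, %d deferred",
                             seed_genus, nrow(boot$training),
                             length(boot$ambiguous), length(boot$deferred)))
  queue <- boot$deferred

  order <- build_iteration_order(genomes, seed_organism,
                                 group_by = config$group_by, dmat = dmat)
  seed_label <- order$groups[[1]]$label
  for (g in order$groups[-1]) {
    if (g$distance >= config$phylum_gap_warn)
      warnf("group '%s' is at XerCD distance %.2f >= %.2f from the seed; profile transfer may be unreliable",
            g$label, g$distance, config$phylum_gap_warn)
    ids <- unlist(lapply(g$organisms, function(o)
      names(genomes)[org_of == o]))
    ids <- setdiff(ids, names(state$predictions))
    if (!length(ids)) next
    state <- run_group_iteration(state, genomes[ids],
                                 step = sprintf("group:%s", g$label))
    queue <- c(queue, state$unresolved)
  }

  # ---- fallback cascade -------------------------------------------------
  # (1) class-level pass over unresolved genomes
  if (length(queue) && config$group_by == "genus") {
    classes <- vapply(genomes[queue], function(g) {
      cl <- g$taxonomy$class
      if (is.na(cl)) "unknown" else cl
    }, character(1))
    for (cl in sort(unique(classes))) {
      ids <- queue[classes == cl]
      state <- run_group_iteration(state, genomes[ids],
                                   step = sprintf("class:%s", cl),
                                   method = "profile_class_level")
      queue <- setdiff(queue, setdiff(ids, state$unresolved))
    }
  }

  # (2) alternative seed profile from the k closest predicted genomes
  still <- setdiff(queue, names(state$predictions))
  for (id in still) {
    target_org <- org_of[[id]]
    trained_orgs <- unique(org_of[state$training$chromosome])
    if (!target_org %in% usable_orgs ||
        length(setdiff(trained_orgs, target_org)) < 1) next
    near <- suppressWarnings(nearest_training_genomes(
      target_org, trained_orgs, dmat, k = config$alternative_seed_k))
    tr <- state$training[org_of[state$training$chromosome] %in% near, ,
                         drop = FALSE]
    if (nrow(tr) < 1) next
    alt <- dif_profile(tr[, c("id", "sequence")],
                       pseudocount = config$pseudocount)
    hits <- scan_chromosome(alt, genomes[[id]],
                            reporting_evalue = config$reporting_evalue)
    pred <- validate_candidate(hits[1, ], skews[[id]], config,
                               method = "alternative_seed")
    if (pred$status %in% c("validated", "provisional")) {
      pred$note <- sprintf("alt seed from: %s",
                           paste(near, collapse = "+"))
      state$predictions[[id]] <- pred
      state <- audit_add(state, "fallback", "alternative_seed", id,
                         pred$note)
      queue <- setdiff(queue, id)
    }
  }

  # (3) cross-group prediction with foreign profiles
  still <- setdiff(queue, names(state$predictions))
  if (length(foreign_profiles)) {
    for (id in still) {
      pred <- cross_group_predict(genomes[[id]], foreign_profiles,
                                  skews[[id]], config)
      if (!is.null(pred)) {
        state$predictions[[id]] <- pred
        state <- audit_add(state, "fallback", "cross_group", id, pred$note)
        queue <- setdiff(queue, id)
      }
    }
  }

  # (4) relaxed pass: best own-profile hit as a provisional candidate
  still <- setdiff(queue, names(state$predictions))
  for (id in still) {
    hits <- scan_chromosome(state$profile, genomes[[id]],
                            reporting_evalue = config$reporting_evalue)
    pred <- validate_candidate(hits[1, ], skews[[id]], config,
                               method = "manual_relaxed")
    if (pred$status == "provisional") {
      pred$note <- "relaxed: palindrome+position only"
      state$predictions[[id]] <- pred
      state <- audit_add(state, "fallback", "manual_relaxed", id, "")
    }
  }

  # terminal states
  preds <- state$predictions
  for (id in names(genomes)) {
    if (!id %in% names(preds)) {
      reason <- if (org_of[[id]] %in% no_xer) "no XerC/XerD proteins"
                else "no candidate passed any strategy"
      preds[[id]] <- failed_prediction(genomes[[id]], reason)
    }
  }
  pred_df <- do.call(rbind, preds[names(genomes)])
  pred_df$organism <- org_of[pred_df$chromosome]
  pred_df <- pred_df[, c("organism", setdiff(names(pred_df), "organism"))]
  rownames(pred_df) <- NULL

  structure(list(predictions = pred_df, profile = state$profile,
                 training = state$training,
                 skews = skew_report_table(skews), order = order,
                 audit = state$audit, config = config),
            class = "dif_run")
}

empty_predictions <- function() {
  data.frame(organism = character(), chromosome = character(),
             start = integer(), strand = character(), sequence = character(),
             score = numeric(), evalue = numeric(),
             palindrome_pairs = integer(), check_score = logical(),
             check_evalue = logical(), check_palindrome = logical(),
             check_position = logical(), status = character(),
             method = character(), note = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.dif_run <- function(x, ...) {
  p <- x$predictions
  cat(sprintf("<dif_run> %d chromosome(s): %d validated, %d provisional, %d ambiguous, %d failed\n",
              nrow(p), sum(p$status == "validated"),
              sum(p$status == "provisional"), sum(p$status == "ambiguous"),
              sum(p$status == "failed")))
  if (!is.null(x$training))
    cat(sprintf("  final profile trained on %d sequence(s)\n",
                nrow(x$training)))
  invisible(x)
}

#' @method summary dif_run
#' @export
summary.dif_run <- function(object, ...) {
  print(object)
  p <- object$predictions
  cat("\nby method:\n")
  print(table(p$method, p$status))
  if (nrow(object$audit))
    cat(sprintf("\naudit log: %d event(s)\n", nrow(object$audit)))
  invisible(object)
}
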