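Package: difscan
Title: Phylogeny-Guided Iterated Profile Prediction of Bacterial dif Sites
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the 28-bp dif site of the XerC/XerD chromosome dimer
    resolution system on circular bacterial chromosomes. A seed dif sequence
    is propagated across a clade by iterated profile modelling: fuzzy matching
    bootstraps a training set within the seed genus, an ungapped 28-column
    log-odds profile with exact p-value calibration scans successively more
    distant taxa in decreasing order of XerC/XerD protein similarity, and
    candidates are gated by score and E-value thresholds, leave-one-out
    cross-validation, palindromic complementarity of the recombinase binding
    arms, and replication-origin exclusion. Companion replication-strand
    statistics (cumulative GC skew, origin/terminus shift-points, GC skew
    index, replichore-relative positions, per-position conservation) support
    validation and interpretation, and a synthetic clade generator provides
    fully specified ground-truth studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
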