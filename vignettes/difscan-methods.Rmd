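---
title: "Predicting bacterial dif sites by phylogeny-guided iterated profiling"
author: "difscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial dif sites by phylogeny-guided iterated profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difscan)
```

## The biological problem

Homologous recombination between sister chromosomes leaves a fraction of
replicating bacterial cells with a dimeric chromosome. The XerC/XerD
tyrosine recombinases resolve the dimer at *dif*, a single 28-bp site per
chromosome located near the replication terminus; the FtsK translocase
positions the reaction at the closing septum. A *dif* site has three parts:
an XerC binding arm (positions 1–11), a 6-bp central region, and an XerD
binding arm (positions 18–28). The inner halves of the two arms — positions
7–12 and 17–22 — pair with each other in the functional site, so a genuine
*dif* keeps most of the six Watson–Crick pairs (7,22), (8,21), (9,20),
(10,19), (11,18), (12,17).

Finding *dif* computationally is hard for exactly the reason it is
interesting: 28 bp is too short, and too variable across phyla, for
similarity search. The approach implemented here exploits the observation
that XerC/XerD protein divergence tracks phylogeny: a profile trained on
close relatives transfers reliably over one small phylogenetic step, and
repeating the step accumulates a progressively more diverse model.

## The model

### Profile and scoring

The training set is always a gap-free alignment of 28-mers (fuzzy matching
allows substitutions only), so the profile is an ungapped 28-column model;
insert and delete states would never be used and are omitted. Emissions are

$$e_j(b) = \frac{c_j(b) + q}{n + 4q},$$

with per-base pseudocount $q$ (default 0.5, which keeps degenerate columns
finite while preserving strong preferences at the small $n$ of early
iterations). A window $w$ scores

$$S(w) = \sum_{j=1}^{28} \log_2 \frac{e_j(w_j)}{p(w_j)}$$

bits, where $p$ is the **scanned chromosome's own** mononucleotide
composition, symmetrized with its complement so one null model covers both
strands. Using the local background rather than a uniform one matters in
AT-rich genomes, where a uniform null inflates the apparent information of
AT-rich sites; profiling is known to degrade there and background-relative
scoring is the honest formulation.

### Exact p-values and E-values

Rather than fitting an extreme-value distribution, the tail probability
$P(S \ge t)$ under the background is computed exactly: per-column scores
are discretized to a fixed grid (default 1/1000 bit) and the distribution
of their sum is built by dynamic programming (convolution over columns).
On toy profiles the DP reproduces exhaustive enumeration over all windows
to within numerical noise; refining the grid tenfold moves p-values by
well under 5 %. The E-value is $p \times N$ with $N$ the number of scored
windows on the chromosome — both strands of the full circle, $2L$ minus
any windows containing `N`. This per-chromosome normalization is a
documented choice; a per-database normalization would simply rescale the
threshold.

### Validation of a candidate

A scanned best hit is **validated** when all checks pass:

| check | default | rationale |
|---|---|---|
| bit score | ≥ 10 | standard working threshold for this strategy; configurable |
| E-value | < 1.0e-04 | likewise |
| palindrome pairs | ≥ 4 of 6 | the *B. subtilis* experimental site scores exactly 4, so any stricter rule would reject a confirmed *dif*; configurable, and this choice is deliberate |
| origin distance | ≥ 10 % of L | *dif* function requires a ter-proximal location; the exclusion radius is a design choice, exposed as `ori_exclusion_fraction` |

A hit failing only the score/E thresholds but passing palindrome and
position is reported **provisional** — the automated counterpart of the
manual rescue applied to sub-threshold candidates in practice. On
chromosomes whose GCSI is below the visibility threshold the position
check is skipped: there is no trustworthy origin estimate to measure from.

### Iteration and cross-validation gating

Organisms are grouped by genus (default) or class; a group's distance to
the seed is the minimum over members of the average XerC/XerD distance
(the closest representative — a deliberate choice, robust to
within-group outliers; the aggregate rule is exposed in the
configuration). Groups are visited in ascending distance. After each group the
profile is rebuilt from the enlarged training set, gated by leave-one-out
cross-validation: each training motif must be re-found on its own
chromosome — best hit at the recorded position and strand, above both
thresholds — by a profile trained on all the others. On failure the gate
evicts from the newest additions only: first those failing their own
held-out re-prediction, otherwise all of the round's additions. Evicted
genomes keep their predictions, flagged not-trained-on. The check runs at
every enlargement; eviction as the remedy is a design decision that keeps
the profile conservative without discarding genome-level results.

Protein distances come from pairwise global alignment (BLOSUM62, gap open
10, extend 0.5): one minus identical pairs over aligned columns.
Multiple-alignment-based distances would depend on the aligner and its
guide tree; since only the *ordering* of taxa drives the algorithm, a
deterministic pairwise distance is preferable.
Arguments are canonically ordered before alignment so the distance is
exactly symmetric. The 0.3 inter-phylum distance is used only to warn when
a profile crosses such a gap.

### Fallback cascade

Genomes unresolved after the main pass are retried with, in order:

1. a class-level pass (phyla are sometimes too diverse for genus steps);
2. an alternative seed profile from the `alternative_seed_k = 3` closest
   already-predicted genomes;
3. cross-group prediction with other clades' final profiles — accepted when
   at least two profiles rank the *identical* site best (position, strand
   and sequence; identity, not overlap, is required) and it validates, or
   when a single profile's best hit fully validates; among agreeing or
   validating profiles the highest bit score decides (a documented
   tie-break rule);
4. a relaxed pass emitting provisional candidates.

Every chromosome therefore terminates in exactly one of: validated,
provisional, ambiguous (several equal-distance fuzzy hits — surfaced, never
silently resolved), or failed.

## Replication-strand statistics

The cumulative GC skew assigns +1 to C, −1 to G and accumulates along the
sequence. Because the chromosome is circular, the curve generally does not
close on itself when the two strands are compositionally imbalanced; the
linear drift is removed before locating extrema, which makes
`find_ori_ter()` exactly equivariant under genome rotation. Under the
convention that the leading strand is G-rich, the detrended maximum marks
the origin and the minimum the terminus.

GCSI combines the amplitude of the one-cycle-per-genome Fourier component
of the windowed skew series (4096 balanced windows; normalized by the
$4/\pi$ amplitude of a unit square wave) with the absolute difference in
mean skew between the two replichores delimited by the extrema (normalized
to $[0,1]$), as their geometric mean. Published GC-skew indices pin their
normalization constants inside particular software; this variant is
instead self-calibrated and therefore **not numerically identical** to
them. It is validated on the index's operational uses only — a perfect
square wave scores 1, i.i.d. genomes stay below the 0.05 visibility
threshold, and the index grows monotonically with generator skew strength.

Replichore-relative position maps a locus to a percentage of the
half-genome measured from the antipode of the origin (0 % opposite the
origin, 100 % at it). Spearman correlations (average ranks on ties) relate
*dif* and terminus positions, and GCSI versus their separation.
Chromosomes with GCSI at or above 0.05 are included; the boundary is
included deliberately where the source text is ambiguous about it.

The conservation quantity of a motif set is, per position, the sample
variance (denominator 3) of the four base percentages: 2500 for a
monomorphic position, 0 for a uniform one; the percent-normalized profile
divides by 2500. The denominator-3 variance is the only choice that
gives the reference value of 2500 for composition 100/0/0/0.
For multi-chromosome organisms, profiles are computed per strain and
averaged before normalization.

## The synthetic study generator

`clade_spec()` fixes the study conditions; `evolve_clade()` realizes them.

* **Phylogeny**: a star tree over genera, the genus-*g* ancestor *g*
  branch-units from the root and leaves one unit below — this produces the
  monotone distance gradient the iterated strategy exploits, and makes
  within-genus distances uniformly small.
* **Genomes**: 100 kb (large enough for stable skew statistics and
  realistic E-value normalization, small enough to simulate in bulk),
  GC 0.5, i.i.d. bases within each replichore with leading-strand excess
  `skew_strength × gc` (default 0.25, a visible-to-pronounced skew);
  the terminus is offset from the origin antipode by
  U(−0.12, 0.12) × L — replichores in real chromosomes are unequal, and
  this spread of terminus positions is what makes the *dif*–terminus
  collinearity measurable rather than degenerate.
* **Implants**: one *dif* per chromosome at the terminus ± U(−0.02, 0.02)
  × L (real *dif*–shift-point separations are of this order), random
  strand.
* **Motif evolution**: substitutions at 0.03/site/branch-unit, the XerD
  arm (positions 13–28) slowed by factor 0.5 (the XerD arm is the more
  conserved in nature). A substitution that breaks one of the six checked
  arm pairs is accompanied, with probability 0.8, by a compensatory
  substitution restoring the partner's complementarity — purifying
  selection on arm pairing, without which neutral drift at this rate would
  destroy the palindrome in a fifth of the deepest leaves, something no
  functional site tolerates.
* **Proteins**: 298-residue recombinase-like sequences evolving i.i.d. at
  0.04/site/branch-unit. This is sufficient for the distance-ordering
  property the method needs and is not claimed to be biologically
  realistic otherwise.
* **Negative controls**: an optional fraction of genomes (never the seed
  organism) receive no implant; ground truth records everything.

The generator emulates divergence structure, skew geometry and implant
placement. It does **not** emulate: indel evolution of the motif (the
method assumes a fixed 28-bp length), repeated elements or mobile DNA that
could produce decoy sites, codon structure or real intergenic placement,
within-genome base-composition heterogeneity, or phage-carried *dif*-like
elements. Passing the synthetic study therefore demonstrates the
machinery — ordering, scanning, calibration, gating, fallbacks — not
performance on real genomes with those confounders.

## Numerical choices and degenerate inputs

* Score discretization 1/1000 bit; hit p-values are looked up on the same
  grid that defines the DP, so scan E-values and `score_pvalue()` agree.
* Emissions of zero (possible only at pseudocount 0) score as an effective
  −∞; their probability mass is tracked separately in the DP and never
  reaches a finite threshold.
* Best-hit ties break by lowest start coordinate, then + strand; group
  ties by label; organism ties by name. Two runs with identical inputs
  and configuration produce byte-identical reports.
* Windows containing `N` are unscoreable and skipped everywhere; an `N`
  at a checked palindrome position counts as non-complementary.
* All-A/T chromosomes have no skew curve: `find_ori_ter()` errors, GCSI
  is 0, and the position check is skipped downstream.
* Chromosomes shorter than the window count reduce the GCSI window count
  with a warning; chromosomes shorter than 28 bp are rejected at scan
  time.
* Origin-spanning gene annotations (start > end) are accepted on ingest
  of circular chromosomes but never synthesized by the generator.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline on a 30-genome, 6-genus study
with 100-kb chromosomes (the default `clade_spec()`), plus a smaller
9-genome study for orchestration tests; GCSI calibration uses 100
independent 100-kb null genomes and 20 replicates per skew strength at
50 kb. These sizes were chosen so the whole suite runs in a few minutes
while leaving the statistical assertions (≥ 95 % recovery, null
calibration of the 0.05 threshold, ρ ≥ 0.9 collinearity) comfortably
powered.

## Known limitations

* The profile is ungapped by design; *dif* variants with insertions or
  deletions (e.g. the 31-bp sites of single-recombinase systems) are out
  of scope, as are XerS/XerH systems generally.
* GCSI here is self-calibrated, not any previously published index; only its
  thresholded and ordinal uses are supported.
* Protein distances are pairwise, not tree-based; they order taxa well but
  are not phylogenetic branch lengths.
* The LOOCV eviction policy is one reasonable design among several
  (rejecting the whole group, re-weighting); the gate is isolated in
  `loocv_gate()` to make alternatives easy to swap in.
* Real-genome performance depends on annotation quality for XerC/XerD and
  on taxonomy labels, which the pipeline takes as inputs.
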