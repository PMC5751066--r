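---
title: "Comparative-mapping methods: in silico group construction and downstream expression stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative-mapping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synanchor)
```

## The problem

A draft fish genome assembled from short reads arrives as tens of thousands
of scaffolds, far short of the karyotype. When the species has no genetic
map of its own, two external resources can still order the scaffolds into
chromosome-scale groups: a radiation-hybrid (RH) marker map from a close
relative (here a *Seriola* congener with 24 linkage groups, SQ1–SQ24), and
a chromosome-level reference genome from a model species (medaka, 24
chromosomes, OL1–OL24) whose homology to the relative's linkage groups is
established one to one. Because all three species share the karyotype
n = 24, each scaffold can be tested against *both* resources and placed
where they agree. `synanchor` implements this dual-evidence anchoring as a
reusable pipeline, together with the downstream expression stages the
anchored genome supports: RNA-seq sample QC, differential-expression (DE)
filtering and partitioning, assignment of DE features to groups, and
Fisher-exact GO-term enrichment.

## The anchoring model

Two channels of evidence are extracted from tabular pairwise alignments
(the 12-column "outfmt 6" dialect):

1. **Marker channel.** RH markers are aligned to the scaffolds and kept at
   a stringent e-value strictly below `1e-10`. Each marker's best hit
   (maximal bit score; ties by identity, then lexicographic subject) casts
   a vote for the marker's linkage group on that scaffold, weighted by bit
   score. Bit score is the evidence unit throughout: unlike e-value or
   identity it is additive across hits and length-aware.
2. **Reference channel.** Scaffolds are aligned to the reference genome
   and filtered at the same threshold. A scaffold's chromosome is the one
   with the maximal *summed* bit score over its hits; its representative
   position is the subject-midpoint of its single best hit on that
   chromosome, and its orientation is that hit's strand. A runner-up
   chromosome carrying at least 80% of the winner's mass flags the call as
   ambiguous (flagged, not discarded; the ratio is configurable).

The two channels are reconciled against the fixed 24-pair homology table:

* both channels present and table-consistent → `placed_dual`;
* reference only → `placed_ref_only` (group via inverse table lookup);
* markers only → `placed_rh_only` (ordered after positioned scaffolds by
  smallest supporting marker rank, default orientation `+` since markers
  carry no orientation evidence);
* channels contradicting the table, or an exactly tied marker vote →
  `conflict` (excluded from groups but written to a side table);
* no evidence → `unplaced`.

Within each group, scaffolds are sorted by reference position (ties:
longer scaffold first, then lexicographic id) and concatenated with 100-bp
`N` spacers into a pseudo-chromosome named `SD<n>` after the RH group
number. The spacer length is recorded in the AGP output, so the
construction is fully reversible; 100 bp is the common convention for an
AGP "scaffold" gap of unknown size, not an estimate. Coordinates are
0-based half-open internally and 1-based inclusive in every on-disk format
(BLAST, AGP), with the shift confined to the readers and writers.

Transcripts are subsequently placed on the pseudo-chromosomes under a
deliberately exact filter — percent identity ≥ 100 and e-value ≤ 0 — and
assigned uniquely to the group of their best hit. The zero bound keeps
only placements the aligner could not distinguish from identity; it is
exposed in `evidence_config()` because some aligners report tiny non-zero
e-values for effectively exact matches. Equal-score ties resolve to the
lexicographically smallest group label (string order, so `"SD12" <
"SD3"`); the rule is arbitrary but deterministic and documented.

## Expression stages

The DE stage consumes precomputed tables (feature, log2FC, p, padj) —
count-model fitting is intentionally out of scope. A feature is
significant iff its adjusted p is present and strictly below α = 0.005 and
|log2FC| strictly exceeds 2, the gonad-contrast thresholds; both are
configurable through `de_config()`, and the positive direction is named
explicitly (`positive_direction_label`) because factor-ordering
conventions differ between DE tools and a silent sign flip is the costliest
failure mode of this stage. Missing adjusted p-values are treated as
non-significant, never imputed.

Sample QC works on log2(count + 1)-transformed columns — the simplest
variance-compressing transform, chosen because the upstream transform is
not dictated by the data format; it is applied consistently in the
distance matrix, outlier rule and PCA. Outliers are flagged when a
sample's mean Euclidean distance to the others exceeds the grand mean of
those means by more than k = 2 standard deviations. This z-score rule
stands in for an unparameterized dendrogram cut: it is deterministic,
needs no visual inspection, and requires at least 3 samples (no dispersion
estimate exists below that).

## Enrichment

GO-term enrichment compares a test feature set against a reference set
with a two-tailed Fisher exact test. The two-tailed p uses the
probability-mass method: with margins fixed, sum the hypergeometric
probabilities of every table no more probable than the observed one (a
relative tolerance of 1e-7 guards floating-point ties, matching the
convention of widely used exact-test implementations; the tail-doubling
variant is available behind a flag). By default the reference side of the
2×2 table excludes the test features so the columns are disjoint;
`reference_includes_test = TRUE` restores the inclusive reading. FDR is
controlled by Benjamini–Hochberg step-up over all tested terms, and terms
with q strictly below 0.05 are reported. Terms are tested exactly as
annotated — no GO-graph ancestor propagation.

## What the simulator emulates

`simulation_config()` defines a desk-scale study whose defaults are the
conditions all recovery tests run under: 4 chromosomes × 50 genes
(1000 bp genes, 500 bp spacers), per-gene translocation probability 0.02
and per-chromosome inversion probability 0.1 between the two karyotypes,
fragmentation to a ~10 kb scaffold length scale (200 bp minimum),
noise-free alignments unless `false_hit_rate` is raised, 10 markers per
group, a 2000-feature × 4-vs-4 negative-binomial count matrix (dispersion
0.1) with 5% true effects of |log2FC| = 4, and 100 GO terms at 5% baseline
annotation probability with 2 terms spiked 6-fold among true-effect
features. Baseline expression means are log-normal (meanlog = log(500),
sdlog = 1), representing adequately sequenced libraries: this scale is
what makes a 16-fold effect recoverable at the stated sensitivity by the
stand-in test below; at substantially lower counts the down-regulated half
of effects hits the count floor of a 4-vs-4 design regardless of
dispersion.

Every generator is a pure function of its configuration — identical seeds
give bit-identical output, and the caller's RNG state is untouched.
Sequences are i.i.d. uniform A/C/G/T: alignment is *simulated*, not
executed, so repeat structure, GC bias and paralogy are deliberately
absent. Consequently, passing recovery tests demonstrate that the
reconciliation, ordering and orientation logic is correct under the stated
noise model; they do not demonstrate robustness to repeat-induced
multi-mapping or assembly chimerism in real data.

The simulator's companion DE table is computed by a two-group Welch t-test
on log2(count + 1) with BH adjustment. It is a labeled stand-in that makes
the filtering stage testable end to end — it is not, and does not claim to
be, a negative-binomial GLM fit.

## Numerical and degenerate-input choices

* Strict `<` for the marker e-value filter; `≤` for the transcript bounds
  (an equality criterion). Boundary hits are therefore excluded and
  included respectively, and both choices are tested at the boundary.
* Exact-test degenerate margins (an empty row or column) return p = 1.
* A constant count matrix yields an all-zero PCA, not an error.
* Welch rows with zero variance in both groups get p = 1 when the means
  agree and p = 0 otherwise.
* All tie-breaks (best hit, chromosome vote, scaffold order, transcript
  assignment) resolve lexicographically after the quantitative keys, so
  every stage is permutation-invariant — verified by property tests.

## Problem sizes used by the test suite

The suite exercises: exhaustive exact-test verification on all 135 751
2×2 tables with N ≤ 40 against a binomial-coefficient enumeration oracle;
anchoring recovery on the default 4 × 50-gene genome (one noise-free run
plus ten 5%-false-hit replicates); 1000-record serialization round-trips;
lift-over bijection over every non-gap coordinate of 100 random groups;
and 50-replicate enrichment calibration at 400 features. These sizes give
stable statistics while keeping a full run around half a minute.

## Known limitations

* Rearrangements *within* a group are not detected: ordering trusts the
  reference, so a true inversion in the study species is silently ordered
  by the reference's gene order (the simulator's `inversion_rate` exists
  precisely to quantify this degradation).
* Gap lengths are conventional, not estimated from read pairs.
* Marker-only scaffolds are included by default (`include_rh_only =
  FALSE` excludes them); whether such scaffolds belong in concatenated
  groups is a judgment call, so both behaviors are first-class.
* The published marker table sums to 467 markers while the accompanying
  text says 468; the packaged fixture records both and the discrepancy is
  surfaced by the acceptance script (`table2_marker_total`), not resolved.
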