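---
title: "Methods: ERBS cluster analysis and its synthetic test bed"
author: "erbsCluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERBS cluster analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

Estrogen receptor α (ER) binds thousands of genomic sites after estrogen
exposure, and neighboring binding sites frequently cooperate in driving a
gene's transcriptional response. This package implements the genome-wide
side of that observation: how clustered ER binding sites (ERBS) are, which
clusters carry the sequence and chromatin features that make them
functional, and how those features relate to estrogen-regulated gene
expression.

The pipeline composes six stages, each exposed as an ordinary function:

* `buildClusters(sites, gap)` merges sites whose edge-to-edge gaps are at
  most `gap` into clusters — the connected components of the "gap ≤ d"
  relation per chromosome, identical to `bedtools merge -d`.
* `controlComparison(controls, n, seeds, gap)` subsamples control site
  sets to the ERBS count and recomputes the clustering summary, giving a
  size-matched empirical null for the clustering statistics.
* `annotateErbs(sites, genome, model)` scans each site's full sequence
  for estrogen response elements.
* `markBasalK27ac(sites, k27Peaks)` flags sites overlapping H3K27ac peaks
  measured *without* estrogen (vehicle condition).
* `classifyClusters(x)` labels clusters active / MMP17-like / CISH-like.
* `assignClustersToGenes(x, genes, radius)` plus `classProportions()`,
  `foldchangePartition()` and the tests in the statistics module relate
  clusters to gene regulation classes.

`erbsAnalysis()` runs all stages in memory; `runPipeline()` adds file I/O,
fail-fast input validation and a reproducible run manifest.

# Models and parameters

## Interval conventions

All files are BED-family, 0-based half-open; in memory every interval is a
`GRanges` (1-based closed) and readers/writers convert at the boundary.
Overlap requires at least one shared base: book-ended intervals do not
overlap, but they do merge at any gap parameter (gap 0). The merge gap is
inclusive: sites exactly `d` apart merge. Nearest-neighbor distance is the
edge-to-edge gap (0 for overlapping or abutting sites); because published
descriptions of such distance histograms often leave the convention
implicit, a midpoint-to-midpoint mode is provided
(`nearestNeighborDistances(x, method = "midpoint")`), with edge-to-edge as
the default since it matches the cited closest-site tooling. Windows are
clipped at position 0 on the left; right clipping happens only when
chromosome lengths are supplied.

* `gap` — cluster merge distance, default 10000 bp. "A window containing
  multiple sites" is operationalized as a merged cluster of size ≥ 2;
  merging site windows of ±10 kb is equivalent to edge-merging the sites
  themselves at 10 kb, and the explicit merge command is the convention
  adopted.
* `radius` — gene association window, default 100000 bp either side of
  the single stored TSS. A cluster counts for a gene when its *span
  overlaps* the window; partial overlap at the edge counts (documented
  choice where the boundary behavior is not stated in descriptions of
  this analysis style).

## The ERE model

The full ERE is the palindromic 15-mer `AGGTCAnnnTGACCT`: two `AGGTCA`
half-sites in inverted orientation around a 3-bp unconstrained spacer. A
window is a full-ERE hit when at most `maxMismatch` of its 12 constrained
positions differ from the consensus; the default tolerance of 2 follows
the functional observation that only near-consensus EREs (1–2 mismatches)
contribute to estrogen-driven expression. `N` counts as a mismatch at
constrained positions, the spacer never contributes, and the constrained
consensus is its own reverse complement, so a single forward scan reports
every hit once (strand `+`). Design choices made here, because the
operational definition of a "strong ERE" varies across studies:

* mismatch counting is the single source of truth — no position-weight
  matrix is used, since no matrix is part of the analysis contract and a
  mismatch rule is exactly reproducible; the threshold is exposed via
  `EreModel(maxMismatch = )`.
* the spacer length is fixed at 3 (the canonical ERE); variable-spacer
  scanning is out of scope.
* half-sites must match the hexamer exactly on either strand — no
  tolerance is defined for half-sites anywhere, and exactness keeps the
  feature conservative. Half hits overlapping a full-ERE window are
  excluded from `n_half_sites` so the halves of a full ERE are not
  double-counted.
* whole peak intervals are scanned rather than fixed summit windows: the
  functionally dissected enhancer cores span roughly whole peaks
  (125–225 bp).

## Activity classification

A cluster is **active** iff it has ≥ 1 member with a full ERE and ≥ 1
member overlapping basal H3K27ac — the two may be the same member, and
singleton clusters are classifiable. **MMP17-like** (hierarchical)
requires one member carrying both features; **CISH-like** (synergistic)
requires a full-ERE member and a basal-K27ac member that are distinct
sites (i ≠ j, with no requirement that the K27ac bearer lack an ERE). A
cluster of ≥ 3 members can satisfy both definitions; the census therefore
reports subtype fractions, "both" fractions, and — at the gene level —
"both" under two readings (any qualification, possibly one dual cluster,
versus two distinct clusters), because the natural-language definition is
ambiguous between them. Subtype fractions use active clusters as the
denominator and are reported as `NA`, not 0, when no cluster is active;
the census also reports the same fractions restricted to active clusters
near up-regulated genes, since either denominator is defensible.

## Statistics

`fisherExactTest()` reports the exact conditional p-value (two-sided
extremeness is probability-based — tables whose hypergeometric
probability does not exceed the observed one — the most common
convention, stated because conventions differ) and the *sample* odds
ratio (ad)/(bc), not the conditional MLE that `stats::fisher.test()`
returns as its estimate; the sample estimator is what accompanying
percentages imply (e.g. 28% vs 12% of genes gives (0.28/0.72)/(0.12/0.88)
≈ 2.9). It is `Inf` when bc = 0 with ad > 0 and `NA` when a margin is
zero. The exact conditional confidence interval is carried along for
coverage checks.

The fold-change comparison between independent gene groups uses the
unpaired Wilcoxon rank-sum test by default — the statistically
appropriate test for two independent groups. A signed-rank variant is
selectable (`test = "signedrank"`, applied to the with-group differences
from the without-group median) because analyses of this design are
sometimes reported under the signed-rank name; neither is silently
substituted for the other. Exactness thresholds: rank-sum p-values are
exact for pooled n ≤ 12 without ties, signed-rank for n ≤ 15 nonzero
untied differences; otherwise the normal approximation with tie and
continuity correction is used. Zero differences are dropped; a fully tied
pooled sample yields p = 1. No multiple-testing correction is applied —
the pipeline reports a small, fixed set of individually interpreted
tests.

# The synthetic generator

`simulateRegulatoryLandscape()` emits everything the pipeline consumes —
genome FASTA, sites BED, basal-H3K27ac BED, two control BEDs, gene TSV —
plus a truth record that is *exactly* consistent with the emitted data:

* **Sites.** A fraction `pair_fraction` of sites is placed as neighbor
  pairs with gaps ~ Uniform(0, `pair_gap_max`); the rest are uniform.
  Sites never overlap (rejection sampling with bounded retries; real peak
  sets are non-overlapping after peak calling).
* **Sequences.** Each site gets an i.i.d. random sequence into which a
  full ERE (probability `p_full_ere`, with 0..`full_ere_mismatch_max`
  constrained-position mismatches sampled uniformly) and/or an exact half
  site (probability `p_half_ere`, random orientation) is planted. The
  background portion is resampled until the only ERE hits in the site are
  the planted ones, which makes per-site truth flags exact by
  construction rather than approximately true. The scanner used for this
  cleaning is validated independently (planted-recovery and analytic
  false-positive-rate tests built without the generator).
* **H3K27ac.** With probability `p_basal_k27ac` a site gets an attached
  peak centered on it with twice the site width; `n_background_k27ac`
  background peaks are placed uniformly to create inactive-overlap noise.
  The truth flag is the *realized* overlap with the union of emitted
  peaks, so chance overlaps are truth, not error.
* **Genes.** Regulation classes are fixed fractions (`frac_up`,
  `frac_down`). Up-regulated genes are placed within `radius` of an
  active cluster with probability `pi_active`, all other genes with
  probability `pi_background`; the recorded coupling flag is again the
  realized window overlap after placement. Log2 fold changes:
  Normal(`fc_base_mean`, `fc_sd`) for up genes plus `fc_shift` when
  coupled, the mirror image for down genes, and narrow noise
  (`fc_null_sd`) for unregulated genes — the minimal structure needed to
  exercise the fold-change comparisons.

## Default conditions

The defaults emulate, at reduced scale, the regulatory landscape the
analysis is designed for: `pair_fraction = 0.4` (≈ 40% of sites with a
≤ 10 kb neighbor, the clustered-excess regime), a genome of 8 × 10 Mb so
that 400 uniformly subsampled control sites show a ~5% multi-site window
rate (the chance-proximity level the real controls exhibit),
`p_full_ere = p_basal_k27ac = 0.3` (minority features whose conjunction
makes active clusters a small fraction of all clusters), and gene
coupling `pi_active = 0.28` versus `pi_background = 0.09`, matching the
reported active-cluster proportions near up- versus non-up-regulated
genes. The fold-change model uses `fc_base_mean = 1`, `fc_sd = 0.8`,
`fc_shift = 0.5` — a realistic spread for up-regulated genes with a
half-unit shift for enhancer-coupled genes.

## What the generator does not emulate

Uniform background sequence (no composition bias, repeats or CpG
structure), rectangular peaks with no read-level signal or summit shape,
no chromatin domains or loops constraining enhancer–gene pairing, and
expression coupling that is purely distance-window-based. Passing tests
therefore demonstrate correctness of the *computational contract* — the
pipeline recovers exactly the structure the generator plants — not that
the biological thresholds would be optimal on any particular real data
set.

## Problem sizes and the sparse genome

Multi-replicate experiments (e.g. the parameter-recovery checks: cohorts
of 3000 sites and 2000 genes on a 100 Mb genome, 100 replicate seeds per
arm) dominate the test-suite runtime through genome string construction
rather than through the analysis itself. Two scaling options exist, both
chosen as the package's own problem-size policy: `background = "N"`
fills non-site background with `N`, and `genome_mode = "patch"` stores
the genome as a `PatchGenome` — site sequences over an implicit `N`
background, byte-equivalent to the dense genome (a tested invariant) but
built in space proportional to the sites. Neither changes any analysis
result, because the pipeline reads sequence only at site intervals; dense
uniform background remains the default. Unit tests use small genomes
(2–4 chromosomes of 1–5 Mb); the recovery experiments use the patch
representation.

# Numerical and degenerate-input choices

* Merging is inclusive at the gap (`reduce(min.gapwidth = gap + 1)`), so
  monotonicity in `d` and idempotence hold exactly.
* Sites alone on their chromosome have no nearest-neighbor distance; they
  are omitted from the distances, counted in `n_omitted`, and remain in
  the denominator of `frac_sites_with_neighbor`.
* Subsampling is without replacement with an explicit seed per draw;
  every stochastic operation takes its seed as an argument and restores
  the caller's RNG state.
* `classificationCensus()` reports `NA` fractions when no cluster is
  active; `foldchangePartition()` warns and returns empty groups when no
  up-regulated genes exist; all-zero signed-rank input is an error.
* Gene tables are validated row-by-row with line numbers in error
  messages; duplicate gene ids, malformed strands and non-numeric fold
  changes abort the run before any stage executes.
* `runPipeline()` outputs contain no timestamps; reruns with an identical
  config are byte-identical, and the manifest records input MD5 checksums
  and stage row counts.

# Known limitations

* The mismatch-rule ERE scanner is deliberately simple; motif strength
  differences below the mismatch threshold are invisible to it.
* Activity classification is feature-based only — it does not model the
  mechanism (ER recruitment order, acetylation spreading) that
  distinguishes hierarchical from synergistic behavior experimentally.
* Gene association is window-based; no nearest-gene mode, enhancer–
  promoter loops or expression quantification are included (regulation
  calls and fold changes are inputs).
* Control comparison subsamples user-provided control site sets only;
  genome-wide shuffle nulls are intentionally out of scope.
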