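# erbsCluster

Genome-wide analysis of estrogen receptor α (ER) binding-site clusters in
R/Bioconductor style.

Estrogen-responsive genes are typically controlled by several ER-bound
enhancers acting together. Genome-wide, ER binding sites (ERBS) are not
scattered uniformly: a large fraction have a neighboring site within 10 kb,
and merged clusters of sites are enriched near estrogen up-regulated genes.
Two regulatory features of a cluster predict whether it drives a
transcriptional response: a *full* estrogen response element (ERE) in at
least one member, and histone H3K27 acetylation already present before
estrogen exposure (*basal* H3K27ac). Clusters carrying both are called
**active**, and they come in two architectures — **hierarchical**
(MMP17-like: one member carries both the full ERE and basal H3K27ac) and
**synergistic** (CISH-like: the full ERE and the basal H3K27ac sit on
different members).

`erbsCluster` implements this analysis as a tested, reusable pipeline for
anyone with ChIP-seq peak sets (BED/narrowPeak), a genome FASTA and a gene
table:

1. **Cluster building** — merge sites whose gaps are ≤ *d* (default
   10 kb, `bedtools merge -d` semantics) into clusters; summarize
   nearest-neighbor distances and multi-site window fractions.
2. **Control comparison** — subsample control site sets (e.g. DNase I
   hypersensitive or CTCF sites) to the ERBS count and re-run the same
   clustering summary.
3. **ERE annotation** — scan each site for the palindromic consensus
   `AGGTCAnnnTGACCT`, calling a *full ERE* when at most 2 of the 12
   constrained positions mismatch (spacer positions are free), and exact
   `AGGTCA` hexamers on either strand as *half EREs*.
4. **Activity classification** — flag sites overlapping basal H3K27ac
   peaks; classify each cluster as active / MMP17-like / CISH-like.
5. **Gene association** — a cluster belongs to a gene when its span
   overlaps the ±100 kb window around the gene's TSS; per-class
   proportions (up / down / not regulated) follow.
6. **Statistics** — Fisher's exact test (sample odds ratio
   *ad*/*bc*) for enrichment of cluster features across gene classes, and
   a Wilcoxon rank-sum comparison of log2 fold changes for up-regulated
   genes with versus without a nearby active cluster (a signed-rank
   variant is selectable).
7. **Synthetic data** — `simulateRegulatoryLandscape()` generates a
   genome, sites with planted neighbor pairs and EREs, basal H3K27ac,
   control sets and a coupled gene table, together with a machine-readable
   truth record, so the entire pipeline is testable without external data.

## Worked example

```r
library(erbsCluster)

cfg <- simConfig(n_chroms = 4L, chrom_length = 5e6, n_sites = 150L,
                 n_genes = 300L, seed = 42L)
sim <- simulateRegulatoryLandscape(cfg)
res <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes,
                    controls = sim$controls, controlSeeds = 1:5)

res$cluster_set
#> ErbsClusterSet
#>   150 sites in 111 clusters (gap = 10000 bp)
#>   32 clusters with >= 2 sites (28.8% of clusters)
res$summary
#>  n_sites n_clusters n_multi_clusters frac_sites_with_neighbor frac_multi_windows
#>      150        111               32                0.4733333          0.2882883
res$tests$fisher_up_vs_not_active
#> Fisher's exact test (two.sided)
#>   p-value  = 0.002201043
#>   odds ratio = 4.469388
#>   95% CI   = [ 1.581187 , 11.76611 ]
```

47% of the simulated sites have a neighbor within 10 kb (40% were planted
as pairs; the rest is chance proximity), 29% of clusters contain multiple
sites versus ~8.5% in the subsampled uniform controls
(`res$control_summaries`), and up-regulated genes are enriched for a
nearby active cluster relative to unregulated genes (odds ratio 4.5). The
fold-change comparison (`res$tests$wilcox_fc_active`) is underpowered at
30 up-regulated genes (p = 0.11 here) — cohort-scale behavior is exercised
in the test suite's parameter-recovery checks.

`runPipeline()` is the file-based front end: it reads a flat YAML config
naming the input files, fails fast on malformed inputs, writes every stage
table (annotated sites, clusters BED, classification, gene annotations,
proportions, test results) and a JSON manifest with input checksums and
row counts, and is byte-reproducible for a fixed config.

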