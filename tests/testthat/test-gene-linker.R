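# Cluster-to-gene assignment through TSS windows, per-class proportions,
# and fold-change partitioning.

# build an annotated cluster set from site positions + flags
linkFixture <- function(starts, e, k, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(starts, width = 2000))
  mcols(gr)$has_full_ere <- e
  mcols(gr)$best_full_mismatches <- ifelse(e, 0L, NA_integer_)
  mcols(gr)$n_half_sites <- 0L
  mcols(gr)$basal_k27ac <- k
  buildClusters(gr, 10000)
}

geneFixture <- function(tss, reg, fc = rep(1, length(tss)),
                        chrom = rep("chr1", length(tss))) {
  DataFrame(gene_id = sprintf("g%02d", seq_along(tss)), chrom = chrom,
            tss = as.integer(tss), strand = "+", reg_class = reg,
            log2fc = fc)
}

test_that("window overlap semantics govern assignment", {
  # cluster span 0-based (1,050,000-1,052,000) vs TSS 1,000,000 +/- 100 kb
  cs <- linkFixture(1050001, TRUE, TRUE)
  genes <- geneFixture(c(1000000, 800000), c("up", "not"))
  ann <- assignClustersToGenes(cs, genes, radius = 100000)
  expect_equal(ann$n_clusters_window, c(1L, 0L))
  expect_true(ann$has_active_cluster[1])
  expect_equal(ann$cluster_class, c("active", "none"))
  # cluster entirely beyond tss + 100 kb is not assigned
  cs2 <- linkFixture(1200002, TRUE, TRUE)
  ann2 <- assignClustersToGenes(cs2, geneFixture(1000000, "up"),
                                radius = 100000)
  expect_equal(ann2$n_clusters_window, 0L)
})

test_that("assignments equal the all-pairs window-overlap oracle", {
  set.seed(79)
  for (rep in 1:3) {
    nS <- 120
    starts <- sample.int(5e6, nS)
    cs <- linkFixture(starts, sample(c(TRUE, FALSE), nS, TRUE),
                      sample(c(TRUE, FALSE), nS, TRUE))
    genes <- geneFixture(sample.int(5e6, 80),
                         sample(c("up", "down", "not"), 80, TRUE))
    ann <- assignClustersToGenes(cs, genes, radius = 100000)
    cl <- erbsClusters(cs)
    for (i in seq_len(nrow(genes))) {
      lo <- genes$tss[i] - 100000   # 0-based window [lo, hi)
      hi <- genes$tss[i] + 100000
      want <- which(start(cl) - 1 < hi & end(cl) > lo)
      expect_setequal(ann$cluster_ids[[i]], mcols(cl)$cluster_id[want])
    }
  }
})

test_that("annotations are total and the activity partition is exclusive", {
  set.seed(83)
  starts <- sample.int(3e6, 60)
  cs <- linkFixture(starts, sample(c(TRUE, FALSE), 60, TRUE),
                    sample(c(TRUE, FALSE), 60, TRUE))
  genes <- geneFixture(sample.int(3e6, 50),
                       sample(c("up", "down", "not"), 50, TRUE))
  ann <- assignClustersToGenes(cs, genes)
  expect_equal(nrow(ann), nrow(genes))
  # active / inactive_only / none: mutually exclusive and exhaustive
  expect_true(all(ann$cluster_class %in% c("active", "inactive_only", "none")))
  expect_equal(ann$cluster_class == "inactive_only", ann$has_inactive_only)
  expect_true(all(!(ann$has_active_cluster & ann$has_inactive_only)))
  expect_equal(ann$cluster_class == "none", ann$n_clusters_window == 0L)
  # subtype flags imply activity
  expect_true(all(!ann$has_mmp17_like | ann$has_active_cluster))
  expect_true(all(!ann$has_cish_like | ann$has_active_cluster))
})

test_that("assignments grow monotonically with the radius", {
  set.seed(89)
  starts <- sample.int(2e6, 40)
  cs <- linkFixture(starts, rep(TRUE, 40), rep(TRUE, 40))
  genes <- geneFixture(sample.int(2e6, 30), rep("up", 30))
  small <- assignClustersToGenes(cs, genes, radius = 50000)
  large <- assignClustersToGenes(cs, genes, radius = 150000)
  for (i in seq_len(nrow(genes)))
    expect_true(all(small$cluster_ids[[i]] %in% large$cluster_ids[[i]]))
})

test_that("classProportions counts per regulation class", {
  cs <- linkFixture(c(100001, 102001), c(TRUE, FALSE), c(TRUE, FALSE))
  # both sites one cluster; gene 1 and 2 up (one near), gene 3 not
  genes <- geneFixture(c(100000, 3000000, 100500), c("up", "up", "not"))
  ann <- assignClustersToGenes(cs, genes)
  pr <- classProportions(ann)
  expect_equal(pr$prop_multi_cluster[pr$reg_class == "up"], 0.5)
  expect_equal(pr$prop_active[pr$reg_class == "not"], 1.0)
  expect_equal(pr$n_genes, c(2L, 1L))
})

test_that("foldchangePartition splits up-regulated genes by feature", {
  cs <- linkFixture(c(100001, 102001), c(TRUE, TRUE), c(TRUE, TRUE))
  genes <- geneFixture(c(100000, 99000, 3000000, 3100000),
                       rep("up", 4), fc = c(2, 2.5, 1, 1.2))
  ann <- assignClustersToGenes(cs, genes)
  grp <- foldchangePartition(ann, "multi_cluster")
  expect_setequal(grp$with, c(2, 2.5))
  expect_setequal(grp$without, c(1, 1.2))
  grpA <- foldchangePartition(ann, "active_cluster")
  expect_setequal(grpA$with, c(2, 2.5))
  expect_error(foldchangePartition(ann, "nonsense"))
  # degenerate: no up-regulated genes -> empty groups with a warning
  annNot <- assignClustersToGenes(cs, geneFixture(1000, "not"))
  expect_warning(grp0 <- foldchangePartition(annNot, "multi_cluster"),
                 "no up-regulated")
  expect_equal(lengths(grp0), c(with = 0L, without = 0L))
})

test_that("planted fold-change shift is recovered from the partition", {
  sim <- simulateRegulatoryLandscape(
    tinySimConfig(seed = 97, n_genes = 400L, n_sites = 80L,
                  pi_active = 0.5, fc_shift = 0.6, fc_sd = 0.3))
  res <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes)
  grp <- foldchangePartition(res$annotations, "active_cluster")
  est <- mean(grp$with) - mean(grp$without)
  se <- sqrt(var(grp$with) / length(grp$with) +
               var(grp$without) / length(grp$without))
  expect_lt(abs(est - 0.6), 4 * se)
})
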