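# The synthetic-data generator: determinism, planted-truth consistency,
# forced configurations, and truth comparison.

test_that("identical config and seed give a byte-identical bundle", {
  cfg <- tinySimConfig(seed = 5L)
  a <- simulateRegulatoryLandscape(cfg)
  b <- simulateRegulatoryLandscape(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(granges(a$sites), granges(b$sites))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_identical(as.data.frame(a$truth$sites), as.data.frame(b$truth$sites))
  expect_identical(granges(a$k27_peaks), granges(b$k27_peaks))
  # a different seed changes the landscape
  c <- simulateRegulatoryLandscape(tinySimConfig(seed = 6L))
  expect_false(identical(granges(a$sites), granges(c$sites)))
})

test_that("simulation does not perturb the caller's RNG stream", {
  set.seed(1000)
  before <- runif(1)
  set.seed(1000)
  invisible(simulateRegulatoryLandscape(tinySimConfig(seed = 9L)))
  expect_identical(runif(1), before)
})

test_that("truth flags are consistent with the emitted data", {
  sim <- simulateRegulatoryLandscape(tinySimConfig(seed = 31L))
  res <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes,
                      run_id = sim$run_id)
  tc <- truthCompare(res, sim$truth)
  expect_equal(tc$sites$full_ere_mismatches, 0L)
  expect_equal(tc$sites$best_mismatch_diffs, 0L)
  expect_equal(tc$sites$half_site_mismatches, 0L)
  expect_equal(tc$sites$k27ac_mismatches, 0L)
  expect_equal(tc$clusters$membership_mismatches, 0L)
  expect_equal(tc$classification$active_mismatches, 0L)
  expect_equal(tc$genes$near_active_mismatches, 0L)
  expect_equal(tc$total_discrepancies, 0L)
})

test_that("run identifiers must match in truth comparison", {
  sim <- simulateRegulatoryLandscape(tinySimConfig(seed = 33L))
  res <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes,
                      run_id = "someone_else")
  expect_error(truthCompare(res, sim$truth), "do not match")
})

test_that("forced config: every site full-ERE + K27ac makes every cluster active", {
  sim <- simulateRegulatoryLandscape(
    tinySimConfig(seed = 37L, p_full_ere = 1, full_ere_mismatch_max = 0L,
                  p_basal_k27ac = 1, p_half_ere = 0))
  res <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes)
  expect_true(all(res$classification$active))
  expect_true(all(res$classification$mmp17_like))
  expect_true(all(mcols(res$sites)$has_full_ere))
  expect_true(all(mcols(res$sites)$best_full_mismatches == 0L))
})

test_that("analysis below the planted mismatch tolerance loses exactly those sites", {
  sim <- simulateRegulatoryLandscape(
    tinySimConfig(seed = 41L, n_sites = 80L, p_full_ere = 0.8))
  res1 <- erbsAnalysis(sim$sites, sim$genome, sim$k27_peaks, sim$genes,
                       model = EreModel(maxMismatch = 1L), run_id = sim$run_id)
  tc <- truthCompare(res1, sim$truth)
  nHighMm <- sum(!is.na(sim$truth$sites$planted_mismatches) &
                   sim$truth$sites$planted_mismatches == 2L)
  expect_gt(nHighMm, 0L)
  expect_equal(tc$sites$full_ere_mismatches, nHighMm)
})

test_that("with no planted pairs, neighbor rates fall to the uniform level", {
  # analytic uniform null: P(no neighbor within d) ~ exp(-2 d n / G)
  fracs <- vapply(1:4, function(s) {
    sim <- simulateRegulatoryLandscape(
      tinySimConfig(seed = 200L + s, pair_fraction = 0, n_sites = 100L,
                    n_chroms = 4L, chrom_length = 5e6))
    clusteringSummary(sim$sites, 10000)$frac_sites_with_neighbor
  }, numeric(1))
  expected <- 1 - exp(-2 * 10200 * 100 / 2e7)
  expect_lt(abs(mean(fracs) - expected), 0.1)
})

test_that("writeSimulation emits a bundle the readers round-trip", {
  sim <- simulateRegulatoryLandscape(tinySimConfig(seed = 43L))
  dir <- tempfile("simout")
  paths <- writeSimulation(sim, dir)
  expect_true(all(file.exists(paths)))
  sites <- readPeakBed(paths[["sites"]])
  expect_equal(as.character(seqnames(sites)), as.character(seqnames(sim$sites)))
  expect_equal(start(sites), start(sim$sites))
  expect_equal(end(sites), end(sim$sites))
  expect_equal(names(sites), names(sim$sites))
  genes <- readGeneTable(paths[["genes"]])
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$log2fc, sim$genes$log2fc)
  genome <- readGenomeFasta(paths[["genome"]])
  expect_identical(as.character(genome), as.character(sim$genome))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$counts$sites, length(sim$sites))
  expect_equal(manifest$run_id, sim$run_id)
})

test_that("infeasible configs are rejected up front", {
  expect_error(simConfig(n_sites = 10000L, n_chroms = 1L,
                         chrom_length = 1e6), "infeasible")
  expect_error(simConfig(frac_up = 0.7, frac_down = 0.5), "exceed 1")
  expect_error(simConfig(p_full_ere = 1.2), "probability")
  expect_error(simConfig(site_width = 30L), "60 bp")
})
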