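# Synthetic regulatory-landscape generator.  Emits a genome, an ERBS-like
# site set with planted clustering, EREs planted in site sequences, basal
# H3K27ac peaks over a subset of sites, uniform control site sets, and a
# gene table whose expression responses are statistically coupled to
# nearby active clusters -- plus a machine-readable truth record that is
# consistent with the emitted data by construction.

#' Simulation configuration
#'
#' Builds and validates the parameter list for
#' [simulateRegulatoryLandscape()].  Defaults emulate, at reduced scale,
#' the regulatory landscape the cluster analysis assumes: an excess of
#' sub-10 kb neighbor pairs over uniform placement, full/half EREs planted
#' in a subset of site sequences, basal H3K27ac over a subset of sites,
#' and up-regulated genes preferentially placed within 100 kb of active
#' clusters (28% coupling for up-regulated genes versus 9% background,
#' matching the proportions the genome-wide analysis reports).
#'
#' @param n_chroms,chrom_length genome shape (default 8 x 10 Mb; at this
#'   density the uniform controls show a ~5% multi-site window rate).
#' @param n_sites number of binding sites (default 400).
#' @param pair_fraction fraction of sites placed as close neighbor pairs
#'   (default 0.4, so ~40% of sites have a neighbor within the gap).
#' @param pair_gap_max planted pair gaps are Uniform(0, pair_gap_max) bp
#'   (default 10000).
#' @param site_width site width in bp (default 200; must be >= 60 so a
#'   full ERE and a separate half-site both fit).
#' @param p_full_ere,p_half_ere per-site planting probabilities.
#' @param full_ere_mismatch_max planted full EREs carry 0..this many
#'   constrained-position mismatches, sampled uniformly (default 2).
#' @param p_basal_k27ac probability a site gets an attached basal H3K27ac
#'   peak (centered on the site, twice its width).
#' @param n_background_k27ac,background_k27_width uniformly placed
#'   background H3K27ac peaks creating inactive-overlap noise.
#' @param n_genes,frac_up,frac_down gene cohort shape.
#' @param pi_active probability an up-regulated gene is placed within
#'   `tss_radius` of an active cluster (default 0.28).
#' @param pi_background the same probability for down-/not-regulated genes
#'   (default 0.09).
#' @param fc_base_mean,fc_shift,fc_sd log2 fold-change model for
#'   up-regulated genes: Normal(fc_base_mean, fc_sd) plus fc_shift when
#'   the gene is near an active cluster.
#' @param fc_null_sd log2 fold-change spread for not-regulated genes.
#' @param gap cluster merge distance in bp (default 10000).
#' @param tss_radius gene association window half-width (default 100000).
#' @param control_multiplier each control set has this multiple of
#'   `n_sites` members (default 3).
#' @param control_width control site width in bp.
#' @param background `"uniform"` (i.i.d. random nucleotides, default) or
#'   `"N"` (N-filled outside sites; the pipeline only ever scans site
#'   sequences, so this mode exists for large multi-replicate designs).
#' @param genome_mode `"dense"` (a `DNAStringSet`, default) or `"patch"`
#'   (a [PatchGenome]: site sequences over an implicit `N` background,
#'   equivalent to `background = "N"` but stored sparsely; use
#'   [materializeGenome()] for FASTA export).
#' @param seed integer seed; the entire bundle is deterministic given the
#'   config.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_chroms = 8L, chrom_length = 1e7, n_sites = 400L,
                      pair_fraction = 0.4, pair_gap_max = 10000L,
                      site_width = 200L, p_full_ere = 0.3,
                      full_ere_mismatch_max = 2L, p_half_ere = 0.3,
                      p_basal_k27ac = 0.3, n_background_k27ac = 1000L,
                      background_k27_width = 600L, n_genes = 500L,
                      frac_up = 0.1, frac_down = 0.1, pi_active = 0.28,
                      pi_background = 0.09, fc_base_mean = 1,
                      fc_shift = 0.5, fc_sd = 0.8, fc_null_sd = 0.2,
                      gap = 10000L, tss_radius = 100000L,
                      control_multiplier = 3L, control_width = 200L,
                      background = c("uniform", "N"),
                      genome_mode = c("dense", "patch"), seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_sites = as.integer(n_sites), pair_fraction = pair_fraction,
    pair_gap_max = as.integer(pair_gap_max),
    site_width = as.integer(site_width), p_full_ere = p_full_ere,
    full_ere_mismatch_max = as.integer(full_ere_mismatch_max),
    p_half_ere = p_half_ere, p_basal_k27ac = p_basal_k27ac,
    n_background_k27ac = as.integer(n_background_k27ac),
    background_k27_width = as.integer(background_k27_width),
    n_genes = as.integer(n_genes), frac_up = frac_up, frac_down = frac_down,
    pi_active = pi_active, pi_background = pi_background,
    fc_base_mean = fc_base_mean, fc_shift = fc_shift, fc_sd = fc_sd,
    fc_null_sd = fc_null_sd, gap = as.numeric(gap),
    tss_radius = as.numeric(tss_radius),
    control_multiplier = as.integer(control_multiplier),
    control_width = as.integer(control_width),
    background = match.arg(background),
    genome_mode = match.arg(genome_mode), seed = as.integer(seed))
  probs <- c("pair_fraction", "p_full_ere", "p_half_ere", "p_basal_k27ac",
             "frac_up", "frac_down", "pi_active", "pi_background")
  for (p in probs)
    if (is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("'", p, "' must be a probability in [0, 1]")
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("frac_up + frac_down must not exceed 1")
  if (cfg$site_width < 60L)
    stop("site_width must be at least 60 bp to accommodate planted motifs")
  if (cfg$full_ere_mismatch_max < 0L || cfg$full_ere_mismatch_max > 12L)
    stop("full_ere_mismatch_max must be in 0..12")
  genomeBp <- cfg$n_chroms * cfg$chrom_length
  if (cfg$n_sites * (cfg$site_width + cfg$pair_gap_max) > 0.5 * genomeBp)
    stop("infeasible config: sites would occupy too much of the genome")
  if (cfg$chrom_length < 2 * (cfg$site_width + cfg$pair_gap_max))
    stop("chrom_length too small for pair placement")
  class(cfg) <- "SimConfig"
  cfg
}

# Sample n positions uniformly within a set of 1-based closed ranges
# (GRanges); returns a GRanges of width-1 points.
.samplePointsInRanges <- function(regions, n) {
  w <- width(regions)
  if (n > 0L && sum(w) == 0) stop("cannot place points in an empty region")
  i <- sample.int(length(regions), n, replace = TRUE, prob = w)
  off <- floor(runif(n) * w[i])
  GRanges(seqnames(regions)[i], IRanges(start(regions)[i] + off, width = 1L))
}

# Place n non-overlapping units (pairs get a partner at gap ~ U(0, gmax))
# by bounded rejection sampling; returns a sorted GRanges of sites.
.placeSites <- function(cfg, seqinfo) {
  nPairs <- floor(cfg$pair_fraction * cfg$n_sites / 2)
  nIso <- cfg$n_sites - 2L * nPairs
  w <- cfg$site_width
  lens <- seqlengths(seqinfo)
  chroms <- names(lens)
  accepted <- GRanges(seqinfo = seqinfo)
  pendingPairs <- nPairs
  pendingIso <- nIso
  for (round in seq_len(100L)) {
    if (pendingPairs == 0L && pendingIso == 0L) break
    cand <- GRanges(seqinfo = seqinfo)
    candUnit <- integer(0)
    if (pendingPairs > 0L) {
      ci <- sample.int(length(chroms), pendingPairs, replace = TRUE, prob = lens)
      maxStart <- lens[ci] - (2L * w + cfg$pair_gap_max) + 1L
      s1 <- 1L + floor(runif(pendingPairs) * maxStart)
      g <- floor(runif(pendingPairs) * (cfg$pair_gap_max + 1L))
      s2 <- s1 + w + g
      cand <- c(cand,
                GRanges(chroms[ci], IRanges(s1, width = w), seqinfo = seqinfo),
                GRanges(chroms[ci], IRanges(s2, width = w), seqinfo = seqinfo))
      candUnit <- c(candUnit, seq_len(pendingPairs), seq_len(pendingPairs))
    }
    if (pendingIso > 0L) {
      ci <- sample.int(length(chroms), pendingIso, replace = TRUE, prob = lens)
      s <- 1L + floor(runif(pendingIso) * (lens[ci] - w + 1L))
      cand <- c(cand, GRanges(chroms[ci], IRanges(s, width = w),
                              seqinfo = seqinfo))
      candUnit <- c(candUnit, pendingPairs + seq_len(pendingIso))
    }
    # a unit is accepted when none of its sites collide with already
    # accepted sites or with sites of an earlier candidate unit
    bad <- unique(candUnit[overlapsAny(cand, accepted)])
    selfHits <- findOverlaps(cand, drop.self = TRUE)
    clash <- candUnit[queryHits(selfHits)] != candUnit[subjectHits(selfHits)]
    laterUnit <- pmax(candUnit[queryHits(selfHits)], candUnit[subjectHits(selfHits)])
    bad <- unique(c(bad, laterUnit[clash]))
    keep <- !candUnit %in% bad
    accepted <- c(accepted, cand[keep])
    nPairUnitsKept <- if (pendingPairs)
      sum(!seq_len(pendingPairs) %in% bad) else 0L
    nIsoUnitsKept <- if (pendingIso)
      sum(!(pendingPairs + seq_len(pendingIso)) %in% bad) else 0L
    pendingPairs <- pendingPairs - nPairUnitsKept
    pendingIso <- pendingIso - nIsoUnitsKept
  }
  if (pendingPairs > 0L || pendingIso > 0L)
    stop("infeasible site placement after bounded retries; ",
         "reduce n_sites or enlarge the genome")
  sites <- sortIntervals(accepted)
  names(sites) <- sprintf("site_%05d", seq_along(sites))
  sites
}

# Build one planted site sequence; returns list(seq, fullOffset, halfOffset).
# Works on raw bytes so thousands of sites (and cleaning retries) are cheap.
.plantSiteSequence <- function(w, full, mism, half, model) {
  consChars <- strsplit(model@fullConsensus, "")[[1L]]
  constrained <- which(consChars != "N")
  bases <- c("A", "C", "G", "T")
  fullOff <- floor((w - length(consChars)) / 2)   # 0-based offset
  halfOff <- 20L
  bytes <- charToRaw(randomDNA(w))
  if (full) {
    motif <- consChars
    motif[consChars == "N"] <- sample(bases, sum(consChars == "N"),
                                      replace = TRUE)
    if (mism > 0L) {
      pos <- sample(constrained, mism)
      for (p in pos) motif[p] <- sample(setdiff(bases, consChars[p]), 1L)
    }
    bytes[(fullOff + 1L):(fullOff + length(motif))] <-
      charToRaw(paste(motif, collapse = ""))
  }
  if (half) {
    hc <- model@halfConsensus
    if (runif(1) < 0.5)
      hc <- paste(rev(strsplit(chartr("ACGT", "TGCA", hc), "")[[1L]]),
                  collapse = "")
    bytes[(halfOff + 1L):(halfOff + nchar(hc))] <- charToRaw(hc)
  }
  list(seq = rawToChar(bytes),
       fullOffset = if (full) fullOff else NA_integer_,
       halfOffset = if (half) halfOff else NA_integer_)
}

# Does a planted sequence scan exactly to its planted truth?
.plantIsClean <- function(seq, planted, mism, mi) {
  bytes <- charToRaw(seq)
  full <- .scanFullRaw(bytes, mi)
  okFull <- if (is.na(planted$fullOffset)) {
    length(full$off0) == 0L
  } else {
    length(full$off0) == 1L && full$off0 == planted$fullOffset &&
      full$mism == mism
  }
  if (!okFull) return(FALSE)
  half <- .scanHalfRaw(bytes, mi, full$off0)
  if (is.na(planted$halfOffset)) length(half$off0) == 0L
  else length(half$off0) == 1L && half$off0 == planted$halfOffset
}

#' Simulate a regulatory landscape with planted ground truth
#'
#' Generates the full input bundle for the pipeline: genome, binding
#' sites (a `pair_fraction` of which are placed as close neighbor pairs,
#' the rest uniformly), site sequences with planted full/half EREs, basal
#' H3K27ac peaks (site-attached plus uniform background), two uniform
#' control site sets, and a gene table whose up-regulated genes are
#' preferentially placed near active clusters and receive a fold-change
#' shift when they are.  Deterministic for a fixed config.
#'
#' Site sequences are rejection-sampled so that the only ERE hits within a
#' site are the planted ones, and basal-K27ac and gene-coupling truth
#' flags are recorded from the realized overlaps; the truth record is
#' therefore exactly consistent with the emitted data.
#'
#' @param cfg A [simConfig()] list.
#' @return A list of class `ErbsSimulation` with elements `genome`
#'   (`DNAStringSet`), `sites`, `k27_peaks`, `controls` (list of two
#'   `GRanges`), `genes` (gene `DataFrame`), `truth` (per-site,
#'   per-cluster and per-gene truth tables plus `run_id` and the config)
#'   and `run_id`.
#' @export
simulateRegulatoryLandscape <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(cfg$seed, {
    chromNames <- paste0("chr", seq_len(cfg$n_chroms))
    si <- Seqinfo(chromNames, rep(cfg$chrom_length, cfg$n_chroms))
    lens <- seqlengths(si)
    model <- EreModel(maxMismatch = cfg$full_ere_mismatch_max)

    ## sites and their planted sequences
    sites <- .placeSites(cfg, si)
    n <- length(sites)
    plantFull <- runif(n) < cfg$p_full_ere
    plantMism <- ifelse(plantFull,
                        sample.int(cfg$full_ere_mismatch_max + 1L, n,
                                   replace = TRUE) - 1L, NA_integer_)
    plantHalf <- runif(n) < cfg$p_half_ere
    mi <- .modelInternals(model)
    seqs <- character(n)
    for (i in seq_len(n)) {
      for (try in seq_len(50L)) {
        pl <- .plantSiteSequence(cfg$site_width, plantFull[i], plantMism[i],
                                 plantHalf[i], model)
        if (.plantIsClean(pl$seq, pl, plantMism[i], mi)) break
        if (try == 50L) stop("could not generate a clean site sequence")
      }
      seqs[i] <- pl$seq
    }

    ## genome assembly: background pieces interleaved with site sequences
    if (cfg$genome_mode == "patch") {
      genome <- PatchGenome(lens, granges(sites), seqs)
    } else {
    chromStrings <- vapply(chromNames, function(ch) {
      len <- lens[[ch]]
      sel <- which(as.character(seqnames(sites)) == ch)
      bg <- function(k) {
        if (k == 0L) ""
        else if (cfg$background == "uniform") randomDNA(k)
        else strrep("N", k)
      }
      if (!length(sel)) return(bg(len))
      s <- start(sites)[sel]
      e <- end(sites)[sel]
      gaps <- c(s[1L] - 1L, s[-1L] - e[-length(e)] - 1L, len - e[length(e)])
      pieces <- character(2L * length(sel) + 1L)
      pieces[seq(1L, by = 2L, length.out = length(sel) + 1L)] <-
        vapply(gaps, bg, character(1))
      pieces[seq(2L, by = 2L, length.out = length(sel))] <- seqs[sel]
      paste(pieces, collapse = "")
    }, character(1))
    genome <- DNAStringSet(chromStrings)
    names(genome) <- chromNames
    }

    ## H3K27ac peaks: site-attached plus uniform background
    attach <- runif(n) < cfg$p_basal_k27ac
    sel <- sites[attach]
    ctr <- floor((start(sel) + end(sel)) / 2)
    attached <- GRanges(seqnames(sel),
                        IRanges(pmax(1L, ctr - cfg$site_width),
                                pmin(lens[as.character(seqnames(sel))],
                                     ctr + cfg$site_width - 1L)),
                        seqinfo = si)
    bgK <- GRanges(seqinfo = si)
    if (cfg$n_background_k27ac > 0L) {
      ci <- sample.int(length(chromNames), cfg$n_background_k27ac,
                       replace = TRUE, prob = lens)
      s <- 1L + floor(runif(cfg$n_background_k27ac) *
                        (lens[ci] - cfg$background_k27_width + 1L))
      bgK <- GRanges(chromNames[ci],
                     IRanges(s, width = cfg$background_k27_width),
                     seqinfo = si)
    }
    k27 <- sortIntervals(c(granges(attached), bgK))
    names(k27) <- sprintf("k27_%05d", seq_along(k27))

    ## realized basal flags and truth clusters
    basal <- as.logical(overlapsAnyInterval(sites, k27))
    truthSites <- sites
    mcols(truthSites)$has_full_ere <- plantFull
    mcols(truthSites)$best_full_mismatches <- plantMism
    mcols(truthSites)$n_half_sites <- as.integer(plantHalf)
    mcols(truthSites)$basal_k27ac <- basal
    cs <- buildClusters(truthSites, cfg$gap)
    classification <- classifyClusters(cs)
    clusterIds <- mcols(erbsClusters(cs))$cluster_id

    ## control site sets (uniform placement, no dedup)
    nCtrl <- cfg$control_multiplier * cfg$n_sites
    makeControl <- function(prefix) {
      ci <- sample.int(length(chromNames), nCtrl, replace = TRUE, prob = lens)
      s <- 1L + floor(runif(nCtrl) * (lens[ci] - cfg$control_width + 1L))
      g <- sortIntervals(GRanges(chromNames[ci],
                                 IRanges(s, width = cfg$control_width),
                                 seqinfo = si))
      names(g) <- sprintf("%s_%05d", prefix, seq_along(g))
      g
    }
    controls <- list(dhs_like = makeControl("dhs"),
                     ctcf_like = makeControl("ctcf"))

    ## genes: class, intended coupling, placement, realized coupling, fc
    nUp <- round(cfg$frac_up * cfg$n_genes)
    nDown <- round(cfg$frac_down * cfg$n_genes)
    regClass <- c(rep("up", nUp), rep("down", nDown),
                  rep("not", cfg$n_genes - nUp - nDown))
    piGene <- ifelse(regClass == "up", cfg$pi_active, cfg$pi_background)
    coupled <- runif(cfg$n_genes) < piGene
    activeSpans <- erbsClusters(cs)[classification$active]
    r <- cfg$tss_radius
    wholeGenome <- GRanges(chromNames, IRanges(1L, lens), seqinfo = si)
    if (length(activeSpans)) {
      nearRegion <- GRanges(seqnames(activeSpans),
                            IRanges(pmax(1L, start(activeSpans) - r + 1L),
                                    pmin(lens[as.character(seqnames(activeSpans))],
                                         end(activeSpans) + r)),
                            seqinfo = si)
      nearRegion <- reduce(nearRegion)
    } else {
      nearRegion <- GRanges(seqinfo = si)
    }
    farRegion <- setdiff(wholeGenome, nearRegion)
    if (any(coupled) && length(nearRegion) == 0L)
      stop("no active clusters to couple genes to; ",
           "raise p_full_ere/p_basal_k27ac or lower pi_active")
    if (any(!coupled) && sum(width(farRegion)) == 0)
      stop("active-cluster windows cover the whole genome; ",
           "cannot place uncoupled genes")
    ptList <- vector("list", 2L)
    if (any(coupled))
      ptList[[1L]] <- .samplePointsInRanges(nearRegion, sum(coupled))
    if (any(!coupled))
      ptList[[2L]] <- .samplePointsInRanges(farRegion, sum(!coupled))
    tss0 <- integer(cfg$n_genes)
    chrom <- character(cfg$n_genes)
    if (any(coupled)) {
      tss0[coupled] <- start(ptList[[1L]]) - 1L
      chrom[coupled] <- as.character(seqnames(ptList[[1L]]))
    }
    if (any(!coupled)) {
      tss0[!coupled] <- start(ptList[[2L]]) - 1L
      chrom[!coupled] <- as.character(seqnames(ptList[[2L]]))
    }
    ## realized coupling: the actual window overlap after placement
    windows <- windowAroundPoint(chrom, tss0, r, seqlengths = lens)
    nearActive <- if (length(activeSpans))
      as.logical(overlapsAnyInterval(windows, activeSpans))
    else rep(FALSE, cfg$n_genes)
    log2fc <- numeric(cfg$n_genes)
    isUp <- regClass == "up"
    isDown <- regClass == "down"
    log2fc[isUp] <- cfg$fc_base_mean + cfg$fc_shift * nearActive[isUp] +
      rnorm(sum(isUp), 0, cfg$fc_sd)
    log2fc[isDown] <- -cfg$fc_base_mean + rnorm(sum(isDown), 0, cfg$fc_sd)
    log2fc[!isUp & !isDown] <- rnorm(sum(!isUp & !isDown), 0, cfg$fc_null_sd)
    genes <- DataFrame(
      gene_id = sprintf("gene_%05d", seq_len(cfg$n_genes)),
      chrom = chrom, tss = tss0,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      reg_class = regClass, log2fc = round(log2fc, 6))

    runId <- sprintf("sim_seed%d_n%d_g%d", cfg$seed, cfg$n_sites, cfg$n_genes)
    truth <- list(
      sites = DataFrame(site = names(sites),
                        planted_full_ere = plantFull,
                        planted_mismatches = plantMism,
                        planted_half = as.integer(plantHalf),
                        basal_k27ac = basal,
                        cluster_id = clusterIds[clusterMembership(cs)]),
      clusters = classification,
      genes = DataFrame(gene_id = genes$gene_id, reg_class = regClass,
                        coupled_intended = coupled,
                        near_active = nearActive, log2fc = genes$log2fc),
      run_id = runId, config = cfg)
    structure(list(genome = genome, sites = granges(sites),
                   k27_peaks = k27, controls = controls, genes = genes,
                   truth = truth, config = cfg, run_id = runId),
              class = "ErbsSimulation")
  })
}

#' @export
print.ErbsSimulation <- function(x, ...) {
  cat("ErbsSimulation", x$run_id, "\n")
  cat(sprintf("  genome: %d chromosomes x %g bp (%s)\n",
              x$config$n_chroms, x$config$chrom_length,
              if (x$config$genome_mode == "patch") "sparse patch representation"
              else paste(x$config$background, "background")))
  cat(sprintf("  %d sites, %d H3K27ac peaks, %d + %d control sites\n",
              length(x$sites), length(x$k27_peaks),
              length(x$controls[[1L]]), length(x$controls[[2L]])))
  cat(sprintf("  %d genes (%d up / %d down), %d truth clusters (%d active)\n",
              nrow(x$genes), sum(x$genes$reg_class == "up"),
              sum(x$genes$reg_class == "down"), nrow(x$truth$clusters),
              sum(x$truth$clusters$active)))
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Emits the standard formats the pipeline reads -- `genome.fa`,
#' `sites.bed`, `k27ac.bed`, one BED per control set, `genes.tsv` -- plus
#' the truth tables as TSV and a JSON manifest.  Byte-identical for a
#' fixed config.
#'
#' @param sim An `ErbsSimulation`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ErbsSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    sites = file.path(dir, "sites.bed"),
    k27ac = file.path(dir, "k27ac.bed"),
    control_dhs_like = file.path(dir, "control_dhs_like.bed"),
    control_ctcf_like = file.path(dir, "control_ctcf_like.bed"),
    genes = file.path(dir, "genes.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_clusters = file.path(dir, "truth_clusters.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeGenomeFasta(materializeGenome(sim$genome), paths[["genome"]])
  writePeakBed(sim$sites, paths[["sites"]])
  writePeakBed(sim$k27_peaks, paths[["k27ac"]])
  writePeakBed(sim$controls$dhs_like, paths[["control_dhs_like"]])
  writePeakBed(sim$controls$ctcf_like, paths[["control_ctcf_like"]])
  writeGeneTable(sim$genes, paths[["genes"]])
  for (nm in c("sites", "clusters", "genes"))
    write.table(as.data.frame(sim$truth[[nm]]),
                paths[[paste0("truth_", nm)]],
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(run_id = sim$run_id,
                   config = unclass(sim$config),
                   counts = list(sites = length(sim$sites),
                                 k27_peaks = length(sim$k27_peaks),
                                 genes = nrow(sim$genes),
                                 clusters = nrow(sim$truth$clusters)))
  write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(paths)
}

#' Compare pipeline outputs against simulation truth
#'
#' Produces per-stage discrepancy counts between an [erbsAnalysis()]
#' result and the truth record of the simulation it was run on: site
#' annotation flags, cluster membership (as a partition), cluster
#' classification, and per-gene active-cluster coupling.  Run identifiers
#' must match when both sides carry one.
#'
#' @param results output of [erbsAnalysis()].
#' @param truth the `truth` element of an `ErbsSimulation`.
#' @return A list of per-stage data.frames plus `total_discrepancies`.
#' @export
truthCompare <- function(results, truth) {
  if (!is.null(results$run_id) && !is.null(truth$run_id) &&
      !identical(results$run_id, truth$run_id))
    stop("run identifiers do not match: ", results$run_id, " vs ",
         truth$run_id)
  ann <- mcols(results$sites)
  ts <- truth$sites
  ord <- match(ts$site, names(results$sites))
  if (anyNA(ord)) stop("site names do not match between results and truth")
  ann <- ann[ord, ]
  sites <- data.frame(
    n_sites = nrow(ts),
    full_ere_mismatches = sum(ann$has_full_ere != ts$planted_full_ere),
    best_mismatch_diffs = sum(!is.na(ts$planted_mismatches) &
                                ann$has_full_ere &
                                (is.na(ann$best_full_mismatches) |
                                   ann$best_full_mismatches != ts$planted_mismatches)),
    half_site_mismatches = sum(ann$n_half_sites != ts$planted_half),
    k27ac_mismatches = sum(ann$basal_k27ac != ts$basal_k27ac))
  ## partition comparison after first-appearance normalization
  canon <- function(x) as.integer(factor(x, levels = unique(x)))
  pipeMem <- canon(clusterMembership(results$cluster_set)[
    match(ts$site, names(erbsSites(results$cluster_set)))])
  truthMem <- canon(as.character(ts$cluster_id))
  clusters <- data.frame(
    n_clusters_pipeline = nrow(results$classification),
    n_clusters_truth = nrow(truth$clusters),
    membership_mismatches = sum(pipeMem != truthMem))
  classif <- data.frame(active_mismatches = NA_integer_,
                        mmp17_mismatches = NA_integer_,
                        cish_mismatches = NA_integer_)
  if (clusters$membership_mismatches == 0L &&
      nrow(results$classification) == nrow(truth$clusters)) {
    pc <- as.data.frame(results$classification)
    tc <- as.data.frame(truth$clusters)
    classif <- data.frame(
      active_mismatches = sum(pc$active != tc$active),
      mmp17_mismatches = sum(pc$mmp17_like != tc$mmp17_like),
      cish_mismatches = sum(pc$cish_like != tc$cish_like))
  }
  tg <- truth$genes
  ga <- results$annotations
  ordg <- match(tg$gene_id, ga$gene_id)
  genes <- data.frame(
    n_genes = nrow(tg),
    near_active_mismatches = sum(ga$has_active_cluster[ordg] != tg$near_active))
  total <- sites$full_ere_mismatches + sites$half_site_mismatches +
    sites$k27ac_mismatches + clusters$membership_mismatches +
    sum(unlist(classif), na.rm = TRUE) + genes$near_active_mismatches
  list(sites = sites, clusters = clusters, classification = classif,
       genes = genes, total_discrepancies = total)
}
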