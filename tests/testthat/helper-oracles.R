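# Independent brute-force oracles used across the suite.  These are
# deliberately naive (all-pairs scans, transitive closures, exhaustive
# enumerations) and share no code with the package implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

# random interval set as a plain data.frame (1-based closed coordinates)
randomIntervalDf <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             maxPos = 1e6, maxWidth = 5000) {
  start <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w - 1L,
             stringsAsFactors = FALSE)
}

dfToGRanges <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  names(gr) <- rownames(df)
  gr
}

# gap in bp between two 1-based closed intervals on the same chromosome
# (0 when they overlap or abut); Inf across chromosomes
pairGap <- function(c1, s1, e1, c2, s2, e2) {
  ifelse(c1 != c2, Inf, pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L))
}

# transitive-closure merge: BFS over the "gap <= d" adjacency
bruteMerge <- function(df, d) {
  n <- nrow(df)
  gaps <- outer(seq_len(n), seq_len(n), function(i, j)
    pairGap(df$chrom[i], df$start[i], df$end[i],
            df$chrom[j], df$start[j], df$end[j]))
  adj <- gaps <= d
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  spans <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = df$chrom[idx[1L]], start = min(df$start[idx]),
               end = max(df$end[idx]), stringsAsFactors = FALSE)
  }))
  spans[order(spans$chrom, spans$start, spans$end), , drop = FALSE]
}

bruteComponents <- function(df, d) {
  n <- nrow(df)
  gaps <- outer(seq_len(n), seq_len(n), function(i, j)
    pairGap(df$chrom[i], df$start[i], df$end[i],
            df$chrom[j], df$start[j], df$end[j]))
  adj <- gaps <= d
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# all-pairs nearest-neighbor gaps; NA for intervals alone on their chrom
bruteNearest <- function(df) {
  n <- nrow(df)
  g <- outer(seq_len(n), seq_len(n), function(i, j)
    pairGap(df$chrom[i], df$start[i], df$end[i],
            df$chrom[j], df$start[j], df$end[j]))
  diag(g) <- Inf
  out <- apply(g, 1L, min)
  ifelse(is.finite(out), out, NA_real_)
}

bruteOverlapsAny <- function(qc, qs, qe, df) {
  any(df$chrom == qc & df$start <= qe & qs <= df$end)
}

# --- naive motif oracles (character-level, no shared code) ---------------

FULL_CONS <- "AGGTCANNNTGACCT"
HALF_CONS <- "AGGTCA"

naiveRevComp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1L]]])), collapse = "")
}

naiveFullScan <- function(seq, maxmm = 2L) {
  cons <- strsplit(FULL_CONS, "")[[1L]]
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(cons)
  hits <- data.frame(offset = integer(0), mismatches = integer(0))
  if (length(chars) < L) return(hits)
  for (o in 0:(length(chars) - L)) {
    mm <- 0L
    for (j in seq_len(L)) {
      if (cons[j] == "N") next
      if (chars[o + j] != cons[j]) mm <- mm + 1L
    }
    if (mm <= maxmm)
      hits <- rbind(hits, data.frame(offset = o, mismatches = mm))
  }
  hits
}

naiveHalfScan <- function(seq, maxmm = 2L) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  rc <- naiveRevComp(HALF_CONS)
  hits <- data.frame(offset = integer(0), strand = character(0))
  if (length(chars) < 6L) return(hits)
  for (o in 0:(length(chars) - 6L)) {
    win <- paste(chars[(o + 1L):(o + 6L)], collapse = "")
    if (win == HALF_CONS)
      hits <- rbind(hits, data.frame(offset = o, strand = "+"))
    if (win == rc)
      hits <- rbind(hits, data.frame(offset = o, strand = "-"))
  }
  full <- naiveFullScan(seq, maxmm)
  if (nrow(full) && nrow(hits)) {
    keep <- vapply(hits$offset, function(o)
      !any(o + 5L >= full$offset & o <= full$offset + 14L), logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  hits
}

# plant the full consensus with `mm` mismatches at 0-based offset `off`
plantFullAt <- function(chars, off, mm) {
  cons <- strsplit(FULL_CONS, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  motif <- cons
  motif[cons == "N"] <- sample(bases, 3L, replace = TRUE)
  if (mm > 0L) {
    for (p in sample(which(cons != "N"), mm))
      motif[p] <- sample(setdiff(bases, cons[p]), 1L)
  }
  chars[(off + 1L):(off + 15L)] <- motif
  chars
}

# --- exact test oracles --------------------------------------------------

# two-sided Fisher p by full enumeration over tables with fixed margins
enumFisherP <- function(a, b, c, d,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  xs <- max(0L, c1 - r2):min(r1, c1)
  pr <- dhyper(xs, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  switch(alternative,
         two.sided = sum(pr[pr <= obs * (1 + 1e-7)]),
         greater = sum(pr[xs >= a]),
         less = sum(pr[xs <= a]))
}

# exact rank-sum p by enumeration over all assignments (no ties assumed);
# replicates the two-sided doubling rule of the exact distribution
enumRankSumP <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(m + n, m)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  pGe <- mean(us >= uObs)
  pLe <- mean(us <= uObs)
  switch(alternative,
         greater = pGe,
         less = pLe,
         two.sided = min(1, 2 * if (uObs > m * n / 2) pGe else pLe))
}

# exact signed-rank p by enumeration over sign patterns (no tied
# magnitudes, no zeros assumed)
enumSignedRankP <- function(d, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pGe <- mean(vs >= vObs)
  pLe <- mean(vs <= vObs)
  switch(alternative,
         greater = pGe,
         less = pLe,
         two.sided = min(1, 2 * if (vObs > n * (n + 1) / 4) pGe else pLe))
}

# truth-table classifier: e[i] = full ERE on member i, k[i] = basal K27ac
bruteClassify <- function(e, k) {
  active <- any(e) && any(k)
  mmp <- any(e & k)
  cish <- FALSE
  for (i in seq_along(e)) for (j in seq_along(k)) {
    if (i != j && e[i] && k[j]) cish <- TRUE
  }
  list(active = active, mmp17 = mmp, cish = cish)
}

# small simulation config used by several files (2 x 1.5 Mb genome)
tinySimConfig <- function(seed = 1L, ...) {
  args <- list(n_chroms = 2L, chrom_length = 1.5e6, n_sites = 50L,
               n_genes = 60L, n_background_k27ac = 40L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}
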