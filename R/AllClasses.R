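#' ERE motif model
#'
#' The estrogen response element (ERE) is modelled as the palindromic
#' 15-mer consensus `AGGTCAnnnTGACCT`: two `AGGTCA` half-sites in inverted
#' orientation around a 3-bp unconstrained spacer.  A *full* ERE match is a
#' 15-bp window whose mismatch count to the consensus, taken over the 12
#' constrained (non-spacer) positions only, is at most `maxMismatch`; `N`
#' counts as a mismatch at constrained positions and the spacer never
#' contributes mismatches.  A *half* ERE is an exact match to the 6-mer
#' half-site on either strand.
#'
#' Because the constrained consensus is its own reverse complement, forward
#' and reverse scans of a sequence report identical full-ERE windows; each
#' window is therefore reported once, on the "+" strand.
#'
#' @slot fullConsensus character; the 15-mer consensus with `N` marking the
#'   spacer positions.
#' @slot halfConsensus character; the 6-mer half-site consensus.
#' @slot maxMismatch integer; maximum mismatches tolerated over the
#'   constrained positions of a full-ERE window (default 2, following the
#'   observation that only near-consensus EREs with 1-2 mismatches drive
#'   estrogen-dependent expression).
#'
#' @seealso [scanFullEre()], [scanHalfEre()], [annotateErbs()]
#' @examples
#' model <- EreModel()
#' model
#' EreModel(maxMismatch = 1L)
#' @name EreModel-class
#' @rdname EreModel
#' @exportClass EreModel
setClass("EreModel",
  representation(
    fullConsensus = "character",
    halfConsensus = "character",
    maxMismatch = "integer"
  ),
  prototype(
    fullConsensus = "AGGTCANNNTGACCT",
    halfConsensus = "AGGTCA",
    maxMismatch = 2L
  )
)

setValidity("EreModel", function(object) {
  msg <- character()
  fc <- object@fullConsensus
  hc <- object@halfConsensus
  if (length(fc) != 1L || grepl("[^ACGTN]", fc))
    msg <- c(msg, "fullConsensus must be one string over {A,C,G,T,N}")
  if (length(hc) != 1L || grepl("[^ACGT]", hc))
    msg <- c(msg, "halfConsensus must be one string over {A,C,G,T}")
  if (length(msg) == 0L) {
    constrained <- which(strsplit(fc, "")[[1]] != "N")
    if (length(constrained) == 0L)
      msg <- c(msg, "fullConsensus has no constrained positions")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fc)))
    if (!identical(rc, fc))
      msg <- c(msg, "fullConsensus must be palindromic (self reverse-complementary with N spacer)")
    mm <- object@maxMismatch
    if (length(mm) != 1L || is.na(mm) || mm < 0L || mm > length(constrained))
      msg <- c(msg, sprintf("maxMismatch must be in 0..%d", length(constrained)))
  }
  if (length(msg)) msg else TRUE
})

#' @param maxMismatch integer in 0..12; mismatch tolerance for full-ERE
#'   windows, counted over constrained positions only.
#' @param fullConsensus,halfConsensus alternative consensus strings; the
#'   full consensus must remain palindromic with `N` spacer positions.
#' @return An `EreModel` object.
#' @rdname EreModel
#' @export
EreModel <- function(maxMismatch = 2L, fullConsensus = "AGGTCANNNTGACCT",
                     halfConsensus = "AGGTCA") {
  new("EreModel", fullConsensus = toupper(fullConsensus),
      halfConsensus = toupper(halfConsensus),
      maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "EreModel", function(object) {
  cat("EreModel\n")
  cat("  full consensus:", object@fullConsensus,
      sprintf("(max %d mismatches over %d constrained positions)\n",
              object@maxMismatch,
              sum(strsplit(object@fullConsensus, "")[[1]] != "N")))
  cat("  half consensus:", object@halfConsensus, "(exact, both strands)\n")
})

#' ERBS cluster set
#'
#' Container produced by [buildClusters()]: the input ER binding sites, the
#' merged cluster spans, and the membership map between them.  Clusters are
#' the connected components of the "gap at most `d`" relation per
#' chromosome, i.e. what `bedtools merge -d` produces; membership is a
#' partition of the sites.
#'
#' @slot sites [GenomicRanges::GRanges] of the (sorted) input sites, with
#'   any annotation metadata columns carried along.
#' @slot clusters [GenomicRanges::GRanges] of merged cluster spans with
#'   metadata columns `cluster_id` and `size`.
#' @slot membership integer vector, one entry per site, giving the row of
#'   `clusters` the site belongs to.
#' @slot gap numeric; the merge gap `d` in bp.
#'
#' @seealso [buildClusters()], [classifyClusters()], [clusteringSummary()]
#' @name ErbsClusterSet-class
#' @rdname ErbsClusterSet
#' @exportClass ErbsClusterSet
setClass("ErbsClusterSet",
  representation(
    sites = "GRanges",
    clusters = "GRanges",
    membership = "integer",
    gap = "numeric"
  )
)

setValidity("ErbsClusterSet", function(object) {
  msg <- character()
  s <- object@sites
  cl <- object@clusters
  mem <- object@membership
  if (length(mem) != length(s))
    msg <- c(msg, "membership must have one entry per site")
  if (!all(c("cluster_id", "size") %in% colnames(mcols(cl))))
    msg <- c(msg, "clusters must carry cluster_id and size metadata columns")
  if (length(object@gap) != 1L || is.na(object@gap) || object@gap < 0)
    msg <- c(msg, "gap must be a single non-negative number")
  if (length(msg) == 0L && length(s)) {
    if (any(is.na(mem)) || any(mem < 1L) || any(mem > length(cl))) {
      msg <- c(msg, "membership indices out of range")
    } else {
      sizes <- tabulate(mem, nbins = length(cl))
      if (!identical(as.integer(sizes), as.integer(mcols(cl)$size)))
        msg <- c(msg, "cluster sizes do not match membership (partition violated)")
      same <- as.character(seqnames(s)) == as.character(seqnames(cl))[mem]
      covered <- same & start(cl)[mem] <= start(s) & end(cl)[mem] >= end(s)
      if (!all(covered))
        msg <- c(msg, "every site must be covered by the span of its cluster")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ErbsClusterSet", function(object) {
  n <- length(object@sites)
  k <- length(object@clusters)
  multi <- sum(mcols(object@clusters)$size >= 2L)
  cat("ErbsClusterSet\n")
  cat(sprintf("  %d sites in %d clusters (gap = %g bp)\n", n, k, object@gap))
  cat(sprintf("  %d clusters with >= 2 sites (%.1f%% of clusters)\n",
              multi, if (k) 100 * multi / k else NA_real_))
  ann <- colnames(mcols(object@sites))
  if (length(ann)) cat("  site annotations:", paste(ann, collapse = ", "), "\n")
})

#' @param x An `ErbsClusterSet`.
#' @return `erbsSites` returns the site `GRanges`; `erbsClusters` the
#'   cluster-span `GRanges`; `clusterMembership` the site-to-cluster index
#'   vector; `clusterSizes` the integer member count per cluster;
#'   `gapParameter` the merge gap in bp.
#' @rdname ErbsClusterSet
#' @export
erbsSites <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  x@sites
}

#' @rdname ErbsClusterSet
#' @export
erbsClusters <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  x@clusters
}

#' @rdname ErbsClusterSet
#' @export
clusterMembership <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  x@membership
}

#' @rdname ErbsClusterSet
#' @export
clusterSizes <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  mcols(x@clusters)$size
}

#' @rdname ErbsClusterSet
#' @export
gapParameter <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  x@gap
}
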