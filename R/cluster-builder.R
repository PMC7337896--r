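# Cluster construction and clustering statistics: merge sites within a gap
# threshold into clusters, summarize how clustered a site set is, and
# re-run the same summary on size-matched random subsamples of control
# site sets.

#' Build ERBS clusters by gap merging
#'
#' Clusters are the connected components of the "gap at most `gap`"
#' relation per chromosome (`bedtools merge -d` semantics); singleton
#' clusters are kept, and cluster membership partitions the input sites.
#'
#' @param sites A `GRanges` of binding sites (annotation metadata columns
#'   are carried into the result).
#' @param gap merge distance `d` in bp (default 10000).
#' @return An [ErbsClusterSet].
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 5001, 30001), width = 200))
#' buildClusters(gr, gap = 10000)
buildClusters <- function(sites, gap = 10000) {
  sites <- sortIntervals(sites)
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("'gap' must be a single non-negative number")
  merged <- reduce(sites, min.gapwidth = gap + 1, ignore.strand = TRUE,
                   with.revmap = TRUE)
  revmap <- mcols(merged)$revmap
  membership <- integer(length(sites))
  membership[unlist(revmap)] <- rep(seq_along(merged), elementNROWS(revmap))
  mcols(merged)$revmap <- NULL
  mcols(merged)$cluster_id <- sprintf("cluster_%05d", seq_along(merged))
  mcols(merged)$size <- as.integer(elementNROWS(revmap))
  new("ErbsClusterSet", sites = sites, clusters = merged,
      membership = membership, gap = as.numeric(gap))
}

#' Clustering summary statistics
#'
#' The genome-wide clustering report: number of sites and clusters, number
#' of multi-site clusters ("windows containing more than one site"), the
#' fraction of sites whose nearest same-chromosome neighbor lies within
#' the gap threshold, and the fraction of clusters with two or more
#' members.  Sites alone on their chromosome count in the denominator of
#' `frac_sites_with_neighbor` but can never have a neighbor.
#'
#' @param sites A `GRanges`, or an [ErbsClusterSet] (in which case its gap
#'   is used and `gap` is ignored).
#' @param gap merge/neighbor distance in bp (default 10000).
#' @return A one-row data.frame with columns `n_sites`, `n_clusters`,
#'   `n_multi_clusters`, `frac_sites_with_neighbor`, `frac_multi_windows`.
#' @export
clusteringSummary <- function(sites, gap = 10000) {
  if (is(sites, "ErbsClusterSet")) {
    cs <- sites
  } else {
    if (length(sites) == 0L) stop("empty site set")
    cs <- buildClusters(sites, gap)
  }
  s <- erbsSites(cs)
  if (length(s) == 0L) stop("empty site set")
  sizes <- clusterSizes(cs)
  if (length(s) >= 2L) {
    nn <- nearestNeighborDistances(s)
    nNeighbor <- sum(nn$distances <= gapParameter(cs))
  } else {
    nNeighbor <- 0L
  }
  data.frame(
    n_sites = length(s),
    n_clusters = length(sizes),
    n_multi_clusters = sum(sizes >= 2L),
    frac_sites_with_neighbor = nNeighbor / length(s),
    frac_multi_windows = sum(sizes >= 2L) / length(sizes))
}

#' Cluster analysis of subsampled control site sets
#'
#' For each control set (e.g. DNase I hypersensitive sites, CTCF sites)
#' and each seed, draws a uniform subsample of `n` sites without
#' replacement and recomputes the clustering summary with the same gap --
#' the size-matched null against which ERBS clustering is compared.
#' Control sets are used as provided (no deduplication of overlapping
#' members).
#'
#' @param controls a named list of `GRanges` control site sets, each with
#'   at least `n` members.
#' @param n subsample size (the number of ERBS).
#' @param seeds integer vector of subsampling seeds.
#' @param gap merge/neighbor distance in bp.
#' @return A data.frame with one row per control set and seed: `control`,
#'   `seed`, plus the [clusteringSummary()] columns.
#' @export
controlComparison <- function(controls, n, seeds, gap = 10000) {
  if (is(controls, "GRanges")) controls <- list(control = controls)
  if (is.null(names(controls)) || any(!nzchar(names(controls))))
    names(controls) <- paste0("control", seq_along(controls))
  rows <- list()
  for (nm in names(controls)) {
    ctrl <- controls[[nm]]
    if (length(ctrl) < n)
      stop(sprintf("control set '%s' has %d sites, fewer than n = %d",
                   nm, length(ctrl), n))
    for (sd in seeds) {
      sub <- subsampleIntervals(ctrl, n, seed = sd)
      sm <- clusteringSummary(sub, gap)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(control = nm, seed = sd, stringsAsFactors = FALSE), sm)
    }
  }
  do.call(rbind, rows)
}
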