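# Activity classification: flag basal H3K27ac on sites, classify clusters
# as active (>=1 full-ERE member AND >=1 basal-K27ac member) and type them
# as hierarchical (MMP17-like: one member carries both features) or
# synergistic (CISH-like: the features sit on distinct members).

#' Flag sites overlapping basal H3K27ac peaks
#'
#' Sets the `basal_k27ac` metadata column to whether each site shares at
#' least 1 bp with a peak from the vehicle/untreated H3K27ac set.
#'
#' @param sites A `GRanges` of sites (typically from [annotateErbs()]).
#' @param k27Peaks A `GRanges` of basal-condition H3K27ac peaks.
#' @return `sites` with `basal_k27ac` filled in.
#' @export
markBasalK27ac <- function(sites, k27Peaks) {
  validateIntervals(sites)
  mcols(sites)$basal_k27ac <- if (length(k27Peaks)) {
    overlapsAnyInterval(sites, k27Peaks)
  } else {
    rep(FALSE, length(sites))
  }
  sites
}

# Pull annotated flags from a cluster set, erroring on unannotated members.
.memberFlags <- function(cs) {
  mc <- mcols(erbsSites(cs))
  e <- mc$has_full_ere
  k <- mc$basal_k27ac
  if (is.null(e) || is.null(k) || anyNA(e) || anyNA(k))
    stop("sites must be annotated (has_full_ere via annotateErbs, ",
         "basal_k27ac via markBasalK27ac) before classification")
  list(e = as.logical(e), k = as.logical(k))
}

#' Classify ERBS clusters by activity and subtype
#'
#' A cluster is *active* when it has at least one member with a full ERE
#' and at least one member overlapping basal H3K27ac (the two may be the
#' same member); singleton clusters are classifiable.  An active cluster
#' is *MMP17-like* (hierarchical) when some single member carries both
#' features, and *CISH-like* (synergistic) when a full-ERE member and a
#' basal-K27ac member exist as distinct sites; a cluster of three or more
#' members can be both.
#'
#' @param x An [ErbsClusterSet] whose sites carry non-missing
#'   `has_full_ere` and `basal_k27ac` flags.
#' @return A [S4Vectors::DataFrame] with one row per cluster:
#'   `cluster_id`, `size`, `n_full_ere_members`, `n_basal_k27ac_members`,
#'   `active`, `mmp17_like`, `cish_like`.
#' @export
classifyClusters <- function(x) {
  stopifnot(is(x, "ErbsClusterSet"))
  fl <- .memberFlags(x)
  mem <- clusterMembership(x)
  k <- length(erbsClusters(x))
  nE <- tabulate(mem[fl$e], nbins = k)
  nK <- tabulate(mem[fl$k], nbins = k)
  nBoth <- tabulate(mem[fl$e & fl$k], nbins = k)
  active <- nE >= 1L & nK >= 1L
  mmp17 <- nBoth >= 1L
  # distinct members i != j with ERE on i and K27ac on j exist unless the
  # only ERE bearer and the only K27ac bearer are one and the same site
  cish <- active & !(nE == 1L & nK == 1L & nBoth == 1L)
  stopifnot(all(mmp17[!active] == FALSE), all(cish[!active] == FALSE))
  DataFrame(cluster_id = mcols(erbsClusters(x))$cluster_id,
            size = clusterSizes(x),
            n_full_ere_members = nE,
            n_basal_k27ac_members = nK,
            active = active,
            mmp17_like = mmp17,
            cish_like = cish)
}

#' Census of cluster classifications
#'
#' Cluster-level counts and subtype fractions (denominator: active
#' clusters), plus, when gene annotations are supplied, the same subtype
#' fractions restricted to active clusters within the TSS window of an
#' up-regulated gene, and per-gene counts of up-regulated genes with
#' MMP17-like-only, CISH-like-only, or both subtypes nearby.  Because a
#' single cluster can satisfy both subtype definitions, the "both" count
#' is reported under two readings: any qualification (one dual cluster
#' suffices) and two distinct clusters.
#'
#' With zero active clusters the subtype fractions are `NA`, not 0.
#'
#' @param classification output of [classifyClusters()].
#' @param annotations optional output of [assignClustersToGenes()].
#' @return A list with elements `clusters` (one-row data.frame of counts
#'   and fractions) and, when annotations are given, `genes` (one-row
#'   data.frame of per-gene counts) and `clusters_near_up` (subtype
#'   fractions among active clusters near up-regulated genes).
#' @export
classificationCensus <- function(classification, annotations = NULL) {
  cl <- as.data.frame(classification)
  nActive <- sum(cl$active)
  frac <- function(num) if (nActive) num / nActive else NA_real_
  clusters <- data.frame(
    n_clusters = nrow(cl),
    n_active = nActive,
    frac_active = if (nrow(cl)) nActive / nrow(cl) else NA_real_,
    frac_mmp17_like = frac(sum(cl$mmp17_like)),
    frac_cish_like = frac(sum(cl$cish_like)),
    frac_both_subtypes = frac(sum(cl$mmp17_like & cl$cish_like)),
    frac_mmp17_only = frac(sum(cl$mmp17_like & !cl$cish_like)),
    frac_cish_only = frac(sum(cl$cish_like & !cl$mmp17_like)))
  out <- list(clusters = clusters)
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations[, setdiff(colnames(annotations), "cluster_ids")])
    up <- ann[ann$reg_class == "up", , drop = FALSE]
    out$genes <- data.frame(
      n_up_genes = nrow(up),
      n_up_mmp17_only = sum(up$has_mmp17_like & !up$has_cish_like),
      n_up_cish_only = sum(up$has_cish_like & !up$has_mmp17_like),
      n_up_both_any = sum(up$has_mmp17_like & up$has_cish_like),
      n_up_both_distinct_clusters = sum(up$has_both_distinct_clusters),
      n_up_both_one_cluster = sum(up$has_both_one_cluster))
    upIds <- unique(unlist(annotations$cluster_ids[ann$reg_class == "up"]))
    nearUp <- cl[cl$cluster_id %in% upIds & cl$active, , drop = FALSE]
    nNearUp <- nrow(nearUp)
    frac2 <- function(num) if (nNearUp) num / nNearUp else NA_real_
    out$clusters_near_up <- data.frame(
      n_active_near_up = nNearUp,
      frac_mmp17_like = frac2(sum(nearUp$mmp17_like)),
      frac_cish_like = frac2(sum(nearUp$cish_like)),
      frac_both_subtypes = frac2(sum(nearUp$mmp17_like & nearUp$cish_like)))
  }
  out
}
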