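# Gene association: a cluster belongs to a gene's neighborhood when its
# span overlaps the +/-100 kb window around the gene's TSS.  Every gene
# receives an annotation row (possibly empty), so per-class proportions
# are computable for up-, down- and not-regulated genes alike.

#' Assign clusters to genes through TSS windows
#'
#' A cluster is in a gene's window iff the cluster span shares at least
#' 1 bp with the `radius`-bp window either side of the TSS (overlap
#' semantics, not containment: a cluster partially overlapping the window
#' edge counts).  When the sites of `x` carry activity annotations (or a
#' `classification` is supplied), per-gene activity columns are filled;
#' otherwise they are `NA`.
#'
#' @param x An [ErbsClusterSet].
#' @param genes A gene `DataFrame` ([readGeneTable()]).
#' @param radius window half-width in bp (default 100000).
#' @param classification optional output of [classifyClusters()]; computed
#'   internally when the sites are annotated.
#' @return A [S4Vectors::DataFrame], one row per gene (totality):
#'   `gene_id`, `reg_class`, `log2fc`, `n_clusters_window`, `cluster_ids`
#'   (a `CharacterList`), `has_multi_cluster`, `has_active_cluster`,
#'   `has_inactive_only`, `cluster_class` (`"active"`, `"inactive_only"`
#'   or `"none"`; the three are mutually exclusive and exhaustive),
#'   `has_mmp17_like`, `has_cish_like`, `has_both_one_cluster`,
#'   `has_both_distinct_clusters`.
#' @export
assignClustersToGenes <- function(x, genes, radius = 100000,
                                  classification = NULL) {
  stopifnot(is(x, "ErbsClusterSet"))
  if (length(radius) != 1L || is.na(radius) || radius <= 0)
    stop("'radius' must be a single positive number")
  if (is.null(classification)) {
    mc <- mcols(erbsSites(x))
    if (!is.null(mc$has_full_ere) && !is.null(mc$basal_k27ac) &&
        !anyNA(mc$has_full_ere) && !anyNA(mc$basal_k27ac))
      classification <- classifyClusters(x)
  }
  cl <- erbsClusters(x)
  windows <- windowAroundPoint(genes$chrom, genes$tss, radius)
  hits <- findOverlaps(windows, cl, ignore.strand = TRUE)
  byGene <- split(subjectHits(hits), factor(queryHits(hits),
                                            levels = seq_len(nrow(genes))))
  sizes <- clusterSizes(x)
  ids <- mcols(cl)$cluster_id
  n <- nrow(genes)
  nClusters <- integer(n)
  multi <- logical(n)
  idList <- vector("list", n)
  act <- mmp <- cis <- bothOne <- bothTwo <- rep(NA, n)
  hasClass <- !is.null(classification)
  if (hasClass) {
    cactive <- classification$active
    cmmp <- classification$mmp17_like
    ccish <- classification$cish_like
  }
  for (i in seq_len(n)) {
    sel <- byGene[[i]]
    nClusters[i] <- length(sel)
    idList[[i]] <- ids[sel]
    multi[i] <- any(sizes[sel] >= 2L)
    if (hasClass) {
      act[i] <- any(cactive[sel])
      mmp[i] <- any(cmmp[sel])
      cis[i] <- any(ccish[sel])
      bothOne[i] <- any(cmmp[sel] & ccish[sel])
      bothTwo[i] <- any(cmmp[sel]) && any(ccish[sel]) &&
        length(unique(c(sel[cmmp[sel]], sel[ccish[sel]]))) >= 2L
    }
  }
  inactiveOnly <- if (hasClass) nClusters > 0L & !act else rep(NA, n)
  clusterClass <- if (hasClass) {
    ifelse(act, "active", ifelse(nClusters > 0L, "inactive_only", "none"))
  } else rep(NA_character_, n)
  DataFrame(gene_id = genes$gene_id,
            reg_class = genes$reg_class,
            log2fc = genes$log2fc,
            n_clusters_window = nClusters,
            cluster_ids = as(idList, "CharacterList"),
            has_multi_cluster = multi,
            has_active_cluster = act,
            has_inactive_only = inactiveOnly,
            cluster_class = clusterClass,
            has_mmp17_like = mmp,
            has_cish_like = cis,
            has_both_one_cluster = bothOne,
            has_both_distinct_clusters = bothTwo)
}

#' Per-class proportions of genes with cluster features
#'
#' For each regulation class, the fraction of genes with at least one
#' multi-site cluster in their window, and the active / inactive-only /
#' no-cluster partition fractions.
#'
#' @param annotations output of [assignClustersToGenes()]; must cover
#'   every gene (it does by construction).
#' @return A data.frame with one row per regulation class present.
#' @export
classProportions <- function(annotations) {
  ann <- annotations
  if (anyNA(ann$gene_id) || any(duplicated(ann$gene_id)))
    stop("annotations must contain one row per gene")
  classes <- intersect(.REG_CLASSES, unique(ann$reg_class))
  rows <- lapply(classes, function(cl) {
    a <- ann[ann$reg_class == cl, ]
    n <- nrow(a)
    data.frame(
      reg_class = cl,
      n_genes = n,
      prop_multi_cluster = mean(a$has_multi_cluster),
      prop_active = mean(a$has_active_cluster),
      prop_inactive_only = mean(a$has_inactive_only),
      prop_no_cluster = mean(a$n_clusters_window == 0L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition up-regulated gene fold changes by cluster features
#'
#' Splits up-regulated genes into those with and without the requested
#' feature in their TSS window and returns the two groups of log2 fold
#' changes, ready for a rank test.
#'
#' @param annotations output of [assignClustersToGenes()].
#' @param key `"multi_cluster"` (at least one cluster of 2+ sites) or
#'   `"active_cluster"` (at least one active cluster).
#' @return A list with numeric elements `with` and `without`.
#' @export
foldchangePartition <- function(annotations,
                                key = c("multi_cluster", "active_cluster")) {
  key <- match.arg(key)
  up <- annotations[annotations$reg_class == "up", ]
  if (nrow(up) == 0L) {
    warning("no up-regulated genes; returning empty groups")
    return(list(with = numeric(0), without = numeric(0)))
  }
  flag <- switch(key,
    multi_cluster = up$has_multi_cluster,
    active_cluster = up$has_active_cluster)
  if (anyNA(flag))
    stop("annotations lack the activity columns needed for key '", key, "'")
  list(with = as.numeric(up$log2fc[flag]),
       without = as.numeric(up$log2fc[!flag]))
}
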