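# Interval algebra on GRanges: the coordinate conventions and primitive
# operations every downstream stage builds on.  Coordinates are BED-style
# 0-based half-open at the file boundary; in memory everything is a GRanges
# (1-based closed), and readers/writers do the conversion.

#' Validate a set of genomic intervals
#'
#' Checks that `x` is a `GRanges` whose ranges all have positive width
#' (the half-open contract `start < end`).  Errors name the offending
#' record.
#'
#' @param x A [GenomicRanges::GRanges].
#' @return `x`, invisibly, if valid.
#' @export
#' @examples
#' validateIntervals(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
validateIntervals <- function(x) {
  if (!is(x, "GRanges"))
    stop("expected a GRanges object, got ", class(x)[1L])
  bad <- which(width(x) < 1L)
  if (length(bad))
    stop("malformed interval (start >= end): ", .rangeLabel(x, bad[1L]))
  invisible(x)
}

#' Sort intervals by (chromosome, start, end)
#'
#' @param x A `GRanges`.
#' @return The same multiset of ranges, ordered by chromosome, start and
#'   end, with strand ignored.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 1), c(20, 5)))
#' sortIntervals(gr)
sortIntervals <- function(x) {
  validateIntervals(x)
  x <- sortSeqlevels(x)
  sort(x, ignore.strand = TRUE)
}

#' Merge intervals separated by at most a gap
#'
#' Gap-tolerant merge with `bedtools merge -d` semantics: two intervals on
#' the same chromosome belong to the same output interval iff they are
#' connected through gaps of at most `gap` bp; overlapping and book-ended
#' intervals always merge.  Output intervals span the union of their
#' members and are pairwise separated by gaps greater than `gap`.
#'
#' @param x A `GRanges` (sorted internally; strand ignored).
#' @param gap non-negative integer merge distance `d` in bp (default
#'   10000, the cluster-building distance used throughout the package).
#' @return A `GRanges` of merged intervals, sorted.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5302), c(300, 5600)))
#' mergeWithGap(gr, gap = 10000)   # one interval: gap 5001 <= 10000
#' mergeWithGap(gr, gap = 5000)    # two intervals
mergeWithGap <- function(x, gap = 10000) {
  validateIntervals(x)
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("'gap' must be a single non-negative number")
  reduce(sortIntervals(x), min.gapwidth = gap + 1, ignore.strand = TRUE)
}

#' Nearest-neighbor distances between intervals
#'
#' For each interval that has at least one other interval on the same
#' chromosome, the distance to its closest neighbor: 0 when the two
#' overlap or abut, otherwise the edge-to-edge gap in bp.  Intervals alone
#' on their chromosome are omitted from the distances and counted
#' separately.  A midpoint mode measures midpoint-to-midpoint distance
#' instead (the reference analysis does not state which convention it
#' used; edge-to-edge matches the default of the cited closest tool and is
#' the default here).
#'
#' @param x A `GRanges` with at least 2 ranges.
#' @param method `"edge"` (default) or `"midpoint"`.
#' @return A list with elements `distances` (numeric, one per interval
#'   with a same-chromosome neighbor, in the order of `x` restricted to
#'   those intervals), `which` (indices into `x` of those intervals) and
#'   `n_omitted` (count of intervals alone on their chromosome).
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 601), c(100, 700)))
#' nearestNeighborDistances(gr)$distances  # 500 500
nearestNeighborDistances <- function(x, method = c("edge", "midpoint")) {
  validateIntervals(x)
  method <- match.arg(method)
  if (length(x) == 0L) stop("empty interval set")
  u <- x
  strand(u) <- "*"
  if (method == "edge") {
    hits <- distanceToNearest(u, select = "arbitrary")
    d <- mcols(hits)$distance
    q <- queryHits(hits)
  } else {
    mid <- floor((start(u) + end(u)) / 2)
    pts <- GRanges(seqnames(u), IRanges(mid, width = 1L))
    hits <- distanceToNearest(pts, select = "arbitrary")
    q <- queryHits(hits)
    d <- abs(mid[q] - mid[subjectHits(hits)])
  }
  list(distances = as.numeric(d), which = q, n_omitted = length(x) - length(q))
}

#' Does a query overlap any interval in a set?
#'
#' Half-open overlap semantics at the BED boundary: intervals sharing at
#' least 1 bp overlap; book-ended intervals do not.
#'
#' @param query A `GRanges` (any length).
#' @param subject A `GRanges`.
#' @return Logical vector, one per query range.
#' @export
overlapsAnyInterval <- function(query, subject) {
  validateIntervals(query)
  validateIntervals(subject)
  overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Uniform subsample of an interval set
#'
#' Samples `n` intervals without replacement, deterministically for a
#' fixed seed; used to size-match control site sets to the ERBS set
#' before re-running the cluster analysis.
#'
#' @param x A `GRanges`.
#' @param n sample size; must not exceed `length(x)`.
#' @param seed integer seed.
#' @return A `GRanges` of `n` intervals (input order preserved).
#' @export
subsampleIntervals <- function(x, n, seed) {
  validateIntervals(x)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a non-negative integer")
  if (n > length(x))
    stop(sprintf("cannot sample %d intervals from a set of %d", n, length(x)))
  idx <- withSeed(seed, sample.int(length(x), n))
  x[sort(idx)]
}

#' Symmetric window around a genomic point
#'
#' Builds the interval `[max(0, pos - radius), pos + radius)` in 0-based
#' half-open coordinates (so `pos` is a 0-based position, as stored in the
#' gene table); the left edge is clipped at the chromosome start, and at
#' the chromosome end only when `seqlengths` are supplied.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions (e.g. TSSs).
#' @param radius positive window half-width in bp (default 100000, the
#'   TSS window used for cluster-to-gene assignment).
#' @param seqlengths optional named vector of chromosome lengths for
#'   right-edge clipping.
#' @return A `GRanges` of windows, one per input point.
#' @export
#' @examples
#' windowAroundPoint("chr1", 500000, 100000)  # chr1:400000-600000 (0-based)
#' windowAroundPoint("chr1", 50000, 100000)   # left-clipped at 0
windowAroundPoint <- function(chrom, pos, radius = 100000, seqlengths = NULL) {
  if (length(radius) != 1L || is.na(radius) || radius <= 0)
    stop("'radius' must be a single positive number")
  if (any(is.na(pos)) || any(pos < 0)) stop("positions must be non-negative")
  start0 <- pmax(0, pos - radius)
  end0 <- pos + radius
  if (!is.null(seqlengths)) {
    ln <- seqlengths[chrom]
    if (any(is.na(ln))) stop("chromosome missing from seqlengths")
    end0 <- pmin(end0, ln)
  }
  GRanges(chrom, IRanges(start0 + 1, end0))
}
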