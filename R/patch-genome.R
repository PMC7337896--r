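#' Sparse patch genome
#'
#' A genome represented as a set of sequence patches over an `N`-filled
#' background: equivalent to a dense `DNAStringSet` in which every base
#' outside the patches is `N`, but stored in space proportional to the
#' patched bases.  The simulator offers this representation for large
#' multi-replicate designs because the analysis pipeline only ever reads
#' sequence at binding-site intervals; [materializeGenome()] expands it to
#' an ordinary `DNAStringSet` (e.g. for FASTA export), and
#' [extractSequence()] accepts either representation interchangeably.
#'
#' @slot seqlens named numeric vector of chromosome lengths.
#' @slot patches `GRanges` of non-overlapping patched intervals.
#' @slot patchSeqs character vector of patch sequences, parallel to
#'   `patches`, each of the patch width.
#'
#' @seealso [extractSequence()], [materializeGenome()]
#' @name PatchGenome-class
#' @rdname PatchGenome
#' @exportClass PatchGenome
setClass("PatchGenome",
  representation(
    seqlens = "numeric",
    patches = "GRanges",
    patchSeqs = "character"
  )
)

setValidity("PatchGenome", function(object) {
  msg <- character()
  if (is.null(names(object@seqlens)) || any(object@seqlens < 1))
    msg <- c(msg, "seqlens must be a named vector of positive lengths")
  if (length(object@patches) != length(object@patchSeqs))
    msg <- c(msg, "one sequence per patch required")
  else if (length(object@patches)) {
    if (!all(nchar(object@patchSeqs) == width(object@patches)))
      msg <- c(msg, "patch sequences must match patch widths")
    if (!all(as.character(seqnames(object@patches)) %in% names(object@seqlens)))
      msg <- c(msg, "patch chromosome absent from seqlens")
    if (any(countOverlaps(object@patches, object@patches) > 1L))
      msg <- c(msg, "patches must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @param seqlens,patches,patchSeqs see the slot descriptions.
#' @return `PatchGenome()` returns a new `PatchGenome`.
#' @rdname PatchGenome
#' @export
PatchGenome <- function(seqlens, patches, patchSeqs) {
  new("PatchGenome", seqlens = seqlens, patches = granges(patches),
      patchSeqs = toupper(patchSeqs))
}

setMethod("show", "PatchGenome", function(object) {
  cat("PatchGenome\n")
  cat(sprintf("  %d chromosomes, %g bp total (N background)\n",
              length(object@seqlens), sum(object@seqlens)))
  cat(sprintf("  %d patches covering %g bp\n", length(object@patches),
              sum(width(object@patches))))
})

# Sequence of arbitrary intervals from a PatchGenome: N background with
# patch content overlaid.
.patchExtract <- function(genome, x) {
  chrom <- as.character(seqnames(x))
  missing <- setdiff(unique(chrom), names(genome@seqlens))
  if (length(missing))
    stop("chromosome absent from genome: ", paste(missing, collapse = ", "))
  bad <- which(start(x) < 1L | end(x) > genome@seqlens[chrom])
  if (length(bad))
    stop("interval out of genome bounds: ", .rangeLabel(x, bad[1L]))
  ## fast path: queries that coincide exactly with patches
  key <- function(gr) paste0(as.character(seqnames(gr)), ":", start(gr),
                             "-", end(gr))
  hitIdx <- match(key(x), key(genome@patches))
  out <- character(length(x))
  exact <- !is.na(hitIdx)
  out[exact] <- genome@patchSeqs[hitIdx[exact]]
  rest <- which(!exact)
  if (length(rest)) {
    ov <- findOverlaps(x[rest], genome@patches, ignore.strand = TRUE)
    ovByQ <- split(subjectHits(ov), factor(queryHits(ov),
                                           levels = seq_along(rest)))
    for (k in seq_along(rest)) {
      i <- rest[k]
      chars <- rep("N", width(x)[i])
      for (j in ovByQ[[k]]) {
        ps <- start(genome@patches)[j]
        pe <- end(genome@patches)[j]
        from <- max(start(x)[i], ps)
        to <- min(end(x)[i], pe)
        chars[(from - start(x)[i] + 1L):(to - start(x)[i] + 1L)] <-
          strsplit(substr(genome@patchSeqs[j], from - ps + 1L, to - ps + 1L),
                   "")[[1L]]
      }
      out[i] <- paste(chars, collapse = "")
    }
  }
  res <- DNAStringSet(out)
  names(res) <- names(x)
  res
}

#' Materialize a patch genome as a DNAStringSet
#'
#' @param genome A [PatchGenome] (a `DNAStringSet` is returned as is).
#' @return A named `DNAStringSet` with `N` outside the patches.
#' @export
materializeGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  stopifnot(is(genome, "PatchGenome"))
  p <- sortIntervals(genome@patches)
  ord <- match(paste0(seqnames(p), ":", start(p)),
               paste0(seqnames(genome@patches), ":", start(genome@patches)))
  seqs <- genome@patchSeqs[ord]
  chromStrings <- vapply(names(genome@seqlens), function(ch) {
    len <- genome@seqlens[[ch]]
    sel <- which(as.character(seqnames(p)) == ch)
    if (!length(sel)) return(strrep("N", len))
    s <- start(p)[sel]
    e <- end(p)[sel]
    gaps <- c(s[1L] - 1L, s[-1L] - e[-length(e)] - 1L, len - e[length(e)])
    pieces <- character(2L * length(sel) + 1L)
    pieces[seq(1L, by = 2L, length.out = length(sel) + 1L)] <-
      vapply(gaps, function(k) strrep("N", k), character(1))
    pieces[seq(2L, by = 2L, length.out = length(sel))] <- seqs[sel]
    paste(pieces, collapse = "")
  }, character(1))
  out <- DNAStringSet(chromStrings)
  names(out) <- names(genome@seqlens)
  out
}
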