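# ERE motif scanning.  A full ERE is a window matching the palindromic
# consensus AGGTCAnnnTGACCT with at most maxMismatch mismatches over the 12
# constrained positions; a half ERE is an exact AGGTCA hexamer on either
# strand.  The scanner works on raw bytes with shifted vector comparisons,
# which keeps whole-peak scanning cheap even for thousands of sites.

#' Reverse complement of a DNA string
#'
#' Alphabet `{A,C,G,T,N}`; `N` maps to `N`; other characters are errors.
#'
#' @param seq single character string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverseComplementDNA("AGGTCA")  # "TGACCT"
reverseComplementDNA <- function(seq) {
  seq <- .checkDNA(seq)
  as.character(reverseComplement(DNAString(seq)))
}

# Mismatch counts of every L-length window of `seq` (uppercase character
# scalar) against consensus bytes at the given constrained positions.
# Returns an integer vector of length nchar(seq) - L + 1 (or length 0).
.windowMismatches <- function(bytes, consBytes, constrained, L) {
  n <- length(bytes)
  nw <- n - L + 1L
  if (nw < 1L) return(integer(0))
  m <- integer(nw)
  for (j in constrained) {
    m <- m + (bytes[j:(j + nw - 1L)] != consBytes[j])
  }
  m
}

# Precomputed byte-level view of an EreModel, so tight scanning loops do
# not rebuild Biostrings objects per sequence.
.modelInternals <- function(model) {
  cons <- strsplit(model@fullConsensus, "")[[1L]]
  rcHalf <- paste(rev(strsplit(chartr("ACGTN", "TGCAN",
                                      model@halfConsensus), "")[[1L]]),
                  collapse = "")
  list(consBytes = charToRaw(model@fullConsensus),
       constrained = which(cons != "N"),
       Lf = nchar(model@fullConsensus),
       halfF = charToRaw(model@halfConsensus),
       halfR = charToRaw(rcHalf),
       Lh = nchar(model@halfConsensus),
       maxMM = model@maxMismatch)
}

# Full-ERE hits on a raw byte vector: list(off0, mism), offsets 0-based.
.scanFullRaw <- function(bytes, mi) {
  m <- .windowMismatches(bytes, mi$consBytes, mi$constrained, mi$Lf)
  hit <- which(m <= mi$maxMM)
  list(off0 = hit - 1L, mism = m[hit])
}

# Half-site hits (exact, both strands) with full-window exclusion:
# list(off0, strand).
.scanHalfRaw <- function(bytes, mi, fullOff0 = integer(0)) {
  fwd <- which(.windowMismatches(bytes, mi$halfF, seq_len(mi$Lh), mi$Lh) == 0L) - 1L
  rev <- which(.windowMismatches(bytes, mi$halfR, seq_len(mi$Lh), mi$Lh) == 0L) - 1L
  off <- c(fwd, rev)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  if (length(off) && length(fullOff0)) {
    keep <- !vapply(off, function(o) {
      any(o + mi$Lh - 1L >= fullOff0 & o <= fullOff0 + mi$Lf - 1L)
    }, logical(1))
    off <- off[keep]
    strand <- strand[keep]
  }
  list(off0 = off, strand = strand)
}

#' Scan a sequence for full-ERE windows
#'
#' Reports every window whose mismatch count over the constrained
#' consensus positions is at most `maxMismatch(model)`.  The constrained
#' consensus is palindromic, so forward and reverse-strand scans find the
#' same windows; each is reported once with strand `"+"`.  `N` in the
#' sequence counts as a mismatch at constrained positions; the spacer
#' positions never contribute.
#'
#' @param seq character string (or `DNAString`) over `{A,C,G,T,N}`.
#' @param model An [EreModel].
#' @return A data.frame with columns `offset` (0-based window start),
#'   `strand`, `kind` (`"full"`) and `mismatches`; zero rows when the
#'   sequence is shorter than the consensus or has no match.
#' @export
#' @examples
#' scanFullEre("AGGTCAGGGTGACCT", EreModel(0L))
scanFullEre <- function(seq, model = EreModel()) {
  stopifnot(is(model, "EreModel"))
  seq <- .checkDNA(as.character(seq))
  hits <- .scanFullRaw(charToRaw(seq), .modelInternals(model))
  data.frame(offset = hits$off0, strand = rep("+", length(hits$off0)),
             kind = rep("full", length(hits$off0)), mismatches = hits$mism,
             stringsAsFactors = FALSE)
}

#' Scan a sequence for half-ERE sites
#'
#' Exact matches to the half-site hexamer on either strand (the half-site
#' is not palindromic, so both orientations are scanned).  Hits whose
#' window overlaps a reported full-ERE window are excluded by default,
#' so half-site counts do not double-count the halves of a full ERE.
#'
#' @param seq character string (or `DNAString`) over `{A,C,G,T,N}`.
#' @param model An [EreModel].
#' @param excludeFull drop half hits overlapping a full-ERE window
#'   (default `TRUE`).
#' @return A data.frame with columns `offset` (0-based), `strand`, `kind`
#'   (`"half"`) and `mismatches` (always 0).
#' @export
#' @examples
#' scanHalfEre("TTAGGTCATT")   # one "+" hit at offset 2
#' scanHalfEre("TTTGACCTTT")   # one "-" hit
scanHalfEre <- function(seq, model = EreModel(), excludeFull = TRUE) {
  stopifnot(is(model, "EreModel"))
  seq <- .checkDNA(as.character(seq))
  mi <- .modelInternals(model)
  bytes <- charToRaw(seq)
  fullOff0 <- if (excludeFull) .scanFullRaw(bytes, mi)$off0 else integer(0)
  hits <- .scanHalfRaw(bytes, mi, fullOff0)
  ord <- order(hits$off0, hits$strand)
  data.frame(offset = hits$off0[ord], strand = hits$strand[ord],
             kind = rep("half", length(hits$off0)),
             mismatches = integer(length(hits$off0)), stringsAsFactors = FALSE)
}

# Scan a vector of site sequences; returns parallel vectors rather than
# per-site data.frames so thousands of sites stay cheap.  Used by
# annotateErbs and by the simulator's sequence cleaning.
.scanSiteSet <- function(seqs, model) {
  mi <- .modelInternals(model)
  n <- length(seqs)
  nFull <- integer(n)
  best <- rep(NA_integer_, n)
  nHalf <- integer(n)
  for (i in seq_len(n)) {
    bytes <- charToRaw(seqs[[i]])
    full <- .scanFullRaw(bytes, mi)
    nFull[i] <- length(full$off0)
    if (nFull[i]) best[i] <- min(full$mism)
    nHalf[i] <- length(.scanHalfRaw(bytes, mi, full$off0)$off0)
  }
  list(n_full = nFull, best = best, n_half = nHalf)
}

#' Annotate ER binding sites with ERE features
#'
#' Scans the full interval of each site (not a fixed summit window: the
#' functional cores dissected at MMP17 and CISH span roughly whole peaks)
#' and records whether a full ERE is present, the best (lowest) mismatch
#' count among full hits, and the number of half-sites outside full-ERE
#' windows.  The `basal_k27ac` column is initialised to `NA` and filled by
#' [markBasalK27ac()].
#'
#' @param sites A `GRanges` of sites, all within genome bounds.
#' @param genome A named `DNAStringSet`.
#' @param model An [EreModel].
#' @return `sites` with metadata columns `has_full_ere`,
#'   `best_full_mismatches` (`NA` when no full hit), `n_half_sites` and
#'   `basal_k27ac`.
#' @export
annotateErbs <- function(sites, genome, model = EreModel()) {
  validateIntervals(sites)
  stopifnot(is(model, "EreModel"))
  seqs <- as.character(extractSequence(genome, sites))
  scans <- .scanSiteSet(seqs, model)
  mcols(sites)$has_full_ere <- scans$n_full > 0L
  mcols(sites)$best_full_mismatches <- scans$best
  mcols(sites)$n_half_sites <- scans$n_half
  if (is.null(mcols(sites)$basal_k27ac))
    mcols(sites)$basal_k27ac <- NA
  sites
}
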