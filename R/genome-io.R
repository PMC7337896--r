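# Readers and writers for the formats the pipeline touches.  BED-family
# parsing goes through rtracklayer (which performs the 0-based half-open to
# 1-based closed conversion); FASTA through Biostrings.  The gene table is
# a bespoke TSV because the analysis unit is "gene with one TSS and one
# regulation call"; a GTF adapter is provided for convenience.

.NARROWPEAK_COLS <- c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")
.BROADPEAK_COLS <- .NARROWPEAK_COLS[1:3]

#' Read a BED-family peak file
#'
#' Supports BED3/BED6, narrowPeak (10 columns) and broadPeak (9 columns);
#' the format is guessed from the file extension unless given.  Extra
#' narrowPeak/broadPeak columns are preserved as metadata columns so they
#' survive a round-trip through [writePeakBed()].
#'
#' @param path file path.
#' @param format one of `"auto"`, `"bed"`, `"narrowPeak"`, `"broadPeak"`.
#' @return A `GRanges`, named from the BED name column when present.
#' @export
readPeakBed <- function(path, format = c("auto", "bed", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(file_ext(path))
    format <- switch(ext, narrowpeak = "narrowPeak", broadpeak = "broadPeak", "bed")
  }
  gr <- switch(format,
    bed = import(path, format = "BED"),
    narrowPeak = import(path, format = "BED", extraCols = .NARROWPEAK_COLS),
    broadPeak = import(path, format = "BED", extraCols = .BROADPEAK_COLS))
  if (!is.null(mcols(gr)$name)) {
    names(gr) <- mcols(gr)$name
    mcols(gr)$name <- NULL
  }
  validateIntervals(gr)
  gr
}

#' Write a BED-family peak file
#'
#' Writes narrowPeak/broadPeak when the metadata columns of `x` carry the
#' corresponding signal columns, BED6/BED3 otherwise.  Coordinates are
#' converted back to 0-based half-open.
#'
#' @param x A `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(x, path) {
  validateIntervals(x)
  mc <- mcols(x)
  if (all(names(.NARROWPEAK_COLS) %in% colnames(mc)) ||
      all(names(.BROADPEAK_COLS) %in% colnames(mc))) {
    isNarrow <- all(names(.NARROWPEAK_COLS) %in% colnames(mc))
    df <- data.frame(
      chrom = as.character(seqnames(x)),
      start = start(x) - 1L,
      end = end(x),
      name = if (!is.null(names(x))) names(x) else ".",
      score = if (!is.null(mc$score)) mc$score else 0,
      strand = ifelse(as.character(strand(x)) == "*", ".", as.character(strand(x))),
      signalValue = mc$signalValue,
      pValue = mc$pValue,
      qValue = mc$qValue,
      stringsAsFactors = FALSE)
    if (isNarrow) df$peak <- mc$peak
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    y <- x
    if (!is.null(names(y))) mcols(y)$name <- names(y)
    export(y, path, format = "BED")
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' Loads a genome as a named `DNAStringSet`; sequence names are truncated
#' at the first whitespace to match BED chromosome fields.  Lowercase is
#' uppercased on load; ambiguity codes other than `N` are rejected because
#' the motif scanner defines matches only over `{A,C,G,T,N}`.
#'
#' @param path FASTA path (a sidecar `.fai` index is allowed but not
#'   required).
#' @return A `DNAStringSet`.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  freq <- alphabetFrequency(g)
  other <- setdiff(colnames(freq), c("A", "C", "G", "T", "N"))
  badBase <- colSums(freq[, other, drop = FALSE])
  if (any(badBase > 0))
    stop("genome contains ambiguity codes other than N: ",
         paste(names(badBase)[badBase > 0], collapse = ", "))
  g
}

#' Write a genome FASTA
#'
#' @param genome A named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Extract sequences for intervals from a genome
#'
#' Requests outside the chromosome bounds are errors, never silent
#' truncation; the returned sequences have exactly `end - start` bases.
#'
#' @param genome A named `DNAStringSet`, or a [PatchGenome].
#' @param x A `GRanges` of intervals within the genome.
#' @return A `DNAStringSet`, one sequence per interval, named from `x`.
#' @export
extractSequence <- function(genome, x) {
  validateIntervals(x)
  if (is(genome, "PatchGenome")) return(.patchExtract(genome, x))
  stopifnot(is(genome, "DNAStringSet"))
  chrom <- as.character(seqnames(x))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome absent from genome: ", paste(missing, collapse = ", "))
  lens <- setNames(width(genome), names(genome))
  bad <- which(start(x) < 1L | end(x) > lens[chrom])
  if (length(bad))
    stop("interval out of genome bounds: ", .rangeLabel(x, bad[1L]))
  out <- vector("list", length(genome))
  ord <- integer(0)
  for (i in seq_along(genome)) {
    sel <- which(chrom == names(genome)[i])
    if (!length(sel)) next
    out[[i]] <- extractAt(genome[[i]], IRanges(start(x)[sel], end(x)[sel]))
    ord <- c(ord, sel)
  }
  res <- do.call(c, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- DNAStringSet()
  res <- res[order(ord)]
  names(res) <- names(x)
  res
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length.
#'
#' @param path file path.
#' @return Named integer vector of lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chromosome-sizes file must have two columns")
  setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

.REG_CLASSES <- c("up", "down", "not")

#' Read a gene table
#'
#' Tab-separated file with header columns `gene_id`, `chrom`, `tss`,
#' `strand`, `reg_class`, `log2fc`: one row per gene, `tss` a 0-based
#' position, `reg_class` the estrogen regulation call (`up`, `down` or
#' `not`, case-insensitive) and `log2fc` the log2 expression fold change
#' in response to E2.  Duplicate gene ids, malformed strands, unknown
#' regulation classes and non-numeric fold changes are rejected with the
#' offending line number.
#'
#' @param path file path.
#' @return A [S4Vectors::DataFrame] with the validated, normalized columns.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("gene_id", "chrom", "tss", "strand", "reg_class", "log2fc")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # account for header
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("duplicate gene_id in gene table: ", df$gene_id[which(dup)[1L]],
         " (line ", line[which(dup)[1L]], ")")
  reg <- tolower(df$reg_class)
  badReg <- which(!reg %in% .REG_CLASSES)
  if (length(badReg))
    stop("unknown reg_class '", df$reg_class[badReg[1L]], "' at line ",
         line[badReg[1L]], " (expected up/down/not)")
  badStrand <- which(!df$strand %in% c("+", "-"))
  if (length(badStrand))
    stop("malformed strand '", df$strand[badStrand[1L]], "' at line ",
         line[badStrand[1L]])
  tss <- suppressWarnings(as.numeric(df$tss))
  badTss <- which(is.na(tss) | tss < 0 | tss != floor(tss))
  if (length(badTss))
    stop("tss must be a non-negative integer at line ", line[badTss[1L]])
  fc <- suppressWarnings(as.numeric(df$log2fc))
  badFc <- which(is.na(fc) & !df$log2fc %in% c("NA", ""))
  if (length(badFc))
    stop("non-numeric log2fc '", df$log2fc[badFc[1L]], "' at line ",
         line[badFc[1L]])
  DataFrame(gene_id = df$gene_id, chrom = df$chrom, tss = as.integer(tss),
            strand = df$strand, reg_class = reg, log2fc = fc)
}

#' Write a gene table
#'
#' @param genes A gene `DataFrame` as returned by [readGeneTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' TSS points for a set of genes
#'
#' One width-1 point per gene at the stored TSS; the strand column is
#' carried along but does not shift the point (the TSS field is already
#' the annotated start).
#'
#' @param genes A gene `DataFrame` ([readGeneTable()]).
#' @return A `GRanges` of width-1 points named by `gene_id`.
#' @export
extractTssPoints <- function(genes) {
  gr <- GRanges(genes$chrom, IRanges(genes$tss + 1L, width = 1L),
                strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}

#' Import genes from a GTF annotation
#'
#' Convenience adapter: for each gene, the first transcript (in file
#' order) is taken and its TSS is the strand-aware 5'-most exon boundary,
#' stored 0-based.  Regulation calls and fold changes are not part of GTF;
#' the returned table carries `reg_class = "not"` and `log2fc = NA` for
#' the caller to fill in from expression data.
#'
#' @param path GTF path.
#' @return A gene `DataFrame` with the same columns as [readGeneTable()].
#' @export
genesFromGtf <- function(path) {
  gtf <- import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (!length(ex)) stop("no exon features in GTF: ", path)
  byGene <- split(ex, factor(ex$gene_id, levels = unique(ex$gene_id)))
  rows <- lapply(names(byGene), function(gid) {
    g <- byGene[[gid]]
    g <- g[g$transcript_id == g$transcript_id[1L]]  # first transcript in file order
    minus <- as.character(strand(g)[1L]) == "-"
    tss1 <- if (minus) max(end(g)) else min(start(g))  # strand-aware 5' boundary
    data.frame(gene_id = gid, chrom = as.character(seqnames(g)[1L]),
               tss = as.integer(tss1 - 1L),  # 1-based base -> 0-based position
               strand = if (minus) "-" else "+",
               reg_class = "not", log2fc = NA_real_,
               stringsAsFactors = FALSE)
  })
  DataFrame(do.call(rbind, rows))
}
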