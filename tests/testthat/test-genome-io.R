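# Format round-trips and validation for the genome/gene I/O layer.

test_that("BED6 round-trip preserves the interval set", {
  gr <- GRanges(c("chr1", "chr2"), IRanges(c(101, 501), c(200, 700)),
                strand = c("+", "-"))
  names(gr) <- c("peakA", "peakB")
  mcols(gr)$score <- c(10, 20)
  path <- tempfile(fileext = ".bed")
  writePeakBed(gr, path)
  back <- readPeakBed(path)
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(names(back), names(gr))
  # and the raw file is 0-based half-open
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, start(gr) - 1L)
  expect_equal(raw$V3, end(gr))
  # second round-trip is identical
  path2 <- tempfile(fileext = ".bed")
  writePeakBed(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("narrowPeak columns survive a round-trip", {
  gr <- GRanges("chr1", IRanges(c(1, 1001), c(500, 1500)))
  names(gr) <- c("p1", "p2")
  mcols(gr)$score <- c(100, 200)
  mcols(gr)$signalValue <- c(5.5, 7.25)
  mcols(gr)$pValue <- c(10.1, 12.2)
  mcols(gr)$qValue <- c(8.1, 9.2)
  mcols(gr)$peak <- c(250L, 260L)
  path <- tempfile(fileext = ".narrowPeak")
  writePeakBed(gr, path)
  back <- readPeakBed(path)
  expect_equal(mcols(back)$signalValue, mcols(gr)$signalValue)
  expect_equal(mcols(back)$peak, mcols(gr)$peak)
  expect_equal(start(back), start(gr))
})

test_that("FASTA round-trip and extraction agree with substring indexing", {
  set.seed(23)
  seqs <- c(chrA = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                         collapse = ""),
            chrB = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""))
  genome <- DNAStringSet(seqs)
  path <- tempfile(fileext = ".fa")
  writeGenomeFasta(genome, path)
  back <- readGenomeFasta(path)
  expect_equal(as.character(back), as.character(genome))
  for (i in 1:100) {
    chrom <- sample(names(seqs), 1)
    len <- nchar(seqs[[chrom]])
    s <- sample.int(len - 50L, 1)
    e <- s + sample.int(50L, 1)
    got <- as.character(extractSequence(back, GRanges(chrom, IRanges(s, e))))
    expect_equal(unname(got), substr(seqs[[chrom]], s, e))
  }
})

test_that("sequence extraction errors on bad requests instead of truncating", {
  genome <- DNAStringSet(c(chr1 = "ACGTACGTAC"))
  expect_equal(unname(as.character(
    extractSequence(genome, GRanges("chr1", IRanges(1, 4))))), "ACGT")
  expect_error(extractSequence(genome, GRanges("chr1", IRanges(5, 20))),
               "out of genome bounds")
  expect_error(extractSequence(genome, GRanges("chrX", IRanges(1, 4))),
               "absent")
  # zero-length request violates the interval invariant
  expect_error(extractSequence(genome, GRanges("chr1", IRanges(5, 4))),
               "start >= end")
})

test_that("FASTA loading rejects non-N ambiguity codes and uppercases", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtn"), path)
  expect_equal(unname(as.character(readGenomeFasta(path))), "ACGTN")
  writeLines(c(">chr1", "ACGRT"), path)
  expect_error(readGenomeFasta(path), "ambiguity")
})

test_that("gene tables are validated and normalized", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand\treg_class\tlog2fc",
               "g1\tchr1\t1000\t+\tUP\t1.5",
               "g2\tchr1\t5000\t-\tdown\t-0.7",
               "g3\tchr2\t100\t+\tnot\t0.01"), path)
  genes <- readGeneTable(path)
  expect_equal(nrow(genes), 3L)
  expect_equal(genes$reg_class, c("up", "down", "not"))
  expect_equal(genes$tss, c(1000L, 5000L, 100L))

  writeLines(c("gene_id\tchrom\ttss\tstrand\treg_class\tlog2fc",
               "g1\tchr1\t1000\t+\tup\t1.5",
               "g1\tchr1\t2000\t+\tup\t1.5"), path)
  expect_error(readGeneTable(path), "g1")
  writeLines(c("gene_id\tchrom\ttss\tstrand\treg_class\tlog2fc",
               "g1\tchr1\t1000\t+\tupregulated\t1.5"), path)
  expect_error(readGeneTable(path), "line 2")
  writeLines(c("gene_id\tchrom\ttss\tstrand\treg_class\tlog2fc",
               "g1\tchr1\t1000\t+\tup\t1.5",
               "g2\tchr1\t1000\t*\tup\t1.5"), path)
  expect_error(readGeneTable(path), "strand.*line 3")
  writeLines(c("gene_id\tchrom\ttss\tstrand\treg_class\tlog2fc",
               "g1\tchr1\t1000\t+\tup\thigh"), path)
  expect_error(readGeneTable(path), "log2fc")
})

test_that("TSS points sit at the stored position regardless of strand", {
  genes <- DataFrame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                     tss = c(1000L, 5000L), strand = c("+", "-"),
                     reg_class = c("up", "not"), log2fc = c(1, 0))
  pts <- extractTssPoints(genes)
  expect_equal(start(pts) - 1L, c(1000L, 5000L))  # 0-based positions
  expect_equal(width(pts), c(1L, 1L))
  expect_equal(names(pts), c("g1", "g2"))
})

test_that("GTF adapter takes the strand-aware 5' end of the first transcript", {
  path <- tempfile(fileext = ".gtf")
  lines <- c(
    paste0("chr1\tsrc\texon\t1001\t1200\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1";'),
    paste0("chr1\tsrc\texon\t1500\t1700\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1";'),
    paste0("chr1\tsrc\texon\t900\t950\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t2";'),  # later transcript, ignored
    paste0("chr2\tsrc\texon\t2001\t2200\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "gB.t1";'),
    paste0("chr2\tsrc\texon\t2500\t2600\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "gB.t1";'))
  writeLines(lines, path)
  genes <- genesFromGtf(path)
  expect_equal(genes$gene_id, c("gA", "gB"))
  expect_equal(genes$tss, c(1000L, 2599L))  # 0-based; minus strand uses max end
  expect_equal(genes$strand, c("+", "-"))
})

test_that("chromosome sizes read as a named vector", {
  path <- tempfile()
  writeLines(c("chr1\t1000000", "chr2\t500000"), path)
  sz <- readChromSizes(path)
  expect_equal(sz, c(chr1 = 1000000L, chr2 = 500000L))
})
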