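# Interval algebra against brute-force oracles and the documented
# coordinate conventions.

test_that("sortIntervals orders by (chrom, start, end) and is idempotent", {
  gr <- GRanges(c("chr1", "chr1"), IRanges(c(11, 1), c(20, 5)))
  s <- sortIntervals(gr)
  expect_equal(start(s), c(1, 11))
  expect_identical(sortIntervals(s), s)

  set.seed(42)
  df <- randomIntervalDf(50)
  s2 <- sortIntervals(dfToGRanges(df))
  ord <- order(df$chrom, df$start, df$end)
  expect_equal(as.character(seqnames(s2)), df$chrom[ord])
  expect_equal(start(s2), df$start[ord])
  expect_equal(end(s2), df$end[ord])
})

test_that("malformed intervals are rejected by name", {
  gr <- GRanges("chr1", IRanges(start = c(1, 10), width = c(5, 0)))
  names(gr) <- c("ok", "badpeak")
  expect_error(validateIntervals(gr), "badpeak")
})

test_that("mergeWithGap follows the inclusive gap-merge contract", {
  # 0-based (0,300) and (5300,5600): gap 5000 <= 10000 -> one interval
  gr <- GRanges("chr1", IRanges(c(1, 5301), c(300, 5600)))
  m <- mergeWithGap(gr, 10000)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(1, 5600))
  # gap 14700 > 10000 -> unchanged
  gr2 <- GRanges("chr1", IRanges(c(1, 15001), c(300, 15300)))
  expect_equal(length(mergeWithGap(gr2, 10000)), 2L)
  # gap exactly d merges (inclusive); book-ended merges at d = 0
  gr3 <- GRanges("chr1", IRanges(c(1, 10101), c(100, 10200)))
  expect_equal(length(mergeWithGap(gr3, 10000)), 1L)
  gr4 <- GRanges("chr1", IRanges(c(1, 101), c(100, 200)))
  expect_equal(length(mergeWithGap(gr4, 0)), 1L)
})

test_that("mergeWithGap equals the transitive-closure oracle", {
  set.seed(7)
  for (rep in 1:8) {
    df <- randomIntervalDf(200, maxPos = 3e5)
    gr <- dfToGRanges(df)
    for (d in c(0, 1000, 10000)) {
      m <- mergeWithGap(gr, d)
      oracle <- bruteMerge(df, d)
      expect_equal(as.character(seqnames(m)), oracle$chrom)
      expect_equal(start(m), oracle$start)
      expect_equal(end(m), oracle$end)
    }
  }
})

test_that("mergeWithGap is idempotent, monotone in d, and covers inputs", {
  set.seed(11)
  df <- randomIntervalDf(150)
  gr <- dfToGRanges(df)
  prev <- Inf
  for (d in c(0, 100, 5000, 50000)) {
    m <- mergeWithGap(gr, d)
    expect_identical(granges(mergeWithGap(m, d)), granges(m))
    expect_lte(length(m), prev)
    prev <- length(m)
    # every input bp covered by exactly one output interval
    hits <- countOverlaps(gr, m)
    expect_true(all(hits == 1L))
    expect_true(all(countOverlaps(m, m) == 1L))
    expect_gte(sum(width(intersect(m, gr))), sum(width(reduce(gr))))
  }
})

test_that("nearestNeighborDistances matches the all-pairs oracle", {
  gr <- GRanges("chr1", IRanges(c(1, 601), c(100, 700)))
  expect_equal(nearestNeighborDistances(gr)$distances, c(500, 500))
  grOv <- GRanges("chr1", IRanges(c(1, 51), c(100, 200)))
  expect_equal(nearestNeighborDistances(grOv)$distances, c(0, 0))
  expect_error(nearestNeighborDistances(GRanges()), "empty")

  set.seed(13)
  for (rep in 1:5) {
    df <- randomIntervalDf(100, maxPos = 2e5)
    nn <- nearestNeighborDistances(dfToGRanges(df))
    oracle <- bruteNearest(df)
    expect_equal(nn$n_omitted, sum(is.na(oracle)))
    expect_equal(nn$distances, oracle[nn$which])
    expect_setequal(nn$which, which(!is.na(oracle)))
  }
})

test_that("midpoint mode measures midpoint-to-midpoint distance", {
  gr <- GRanges("chr1", IRanges(c(1, 1001), c(200, 1100)))
  mids <- floor((start(gr) + end(gr)) / 2)
  nn <- nearestNeighborDistances(gr, method = "midpoint")
  expect_equal(nn$distances, rep(abs(diff(mids)), 2))
})

test_that("overlapsAnyInterval uses half-open overlap semantics", {
  # 0-based (10,20) vs (19,30): 1 bp shared -> TRUE
  expect_true(overlapsAnyInterval(GRanges("chr1", IRanges(11, 20)),
                                  GRanges("chr1", IRanges(20, 30))))
  # 0-based (10,20) vs (20,30): book-ended -> FALSE
  expect_false(overlapsAnyInterval(GRanges("chr1", IRanges(11, 20)),
                                   GRanges("chr1", IRanges(21, 30))))
  set.seed(17)
  df <- randomIntervalDf(100)
  qdf <- randomIntervalDf(100)
  got <- overlapsAnyInterval(dfToGRanges(qdf), dfToGRanges(df))
  want <- vapply(seq_len(nrow(qdf)), function(i)
    bruteOverlapsAny(qdf$chrom[i], qdf$start[i], qdf$end[i], df), logical(1))
  expect_equal(got, want)
})

test_that("subsampleIntervals is uniform, seeded, and bounded", {
  gr <- GRanges("chr1", IRanges(seq(1, 1000, by = 100), width = 50))
  expect_identical(granges(subsampleIntervals(gr, length(gr), seed = 1)),
                   granges(gr))
  expect_identical(subsampleIntervals(gr, 3, seed = 99),
                   subsampleIntervals(gr, 3, seed = 99))
  expect_error(subsampleIntervals(gr, 11, seed = 1), "cannot sample")
  # inclusion frequency ~ n/N over many seeds
  counts <- integer(10)
  nSeeds <- 2000
  for (s in seq_len(nSeeds)) {
    idx <- match(start(subsampleIntervals(gr, 5, seed = s)), start(gr))
    counts[idx] <- counts[idx] + 1L
  }
  se <- sqrt(0.5 * 0.5 / nSeeds)
  expect_true(all(abs(counts / nSeeds - 0.5) < 4 * se))
})

test_that("windowAroundPoint builds clipped 0-based half-open windows", {
  w <- windowAroundPoint("chr1", 500000, 100000)
  expect_equal(c(start(w) - 1, end(w)), c(400000, 600000))
  wClip <- windowAroundPoint("chr1", 50000, 100000)
  expect_equal(c(start(wClip) - 1, end(wClip)), c(0, 150000))
  wRight <- windowAroundPoint("chr1", 950000, 100000,
                              seqlengths = c(chr1 = 1e6))
  expect_equal(end(wRight), 1e6)
  set.seed(19)
  pos <- sample.int(1e6, 50)
  ws <- windowAroundPoint("chr1", pos, 2500)
  expect_true(all(width(ws) == 5000 | (pos < 2500 & start(ws) == 1)))
})
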