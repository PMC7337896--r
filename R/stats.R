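# Exact small-sample statistics: Fisher's exact test on 2x2 tables with
# the sample odds ratio, and the two Wilcoxon tests.  P-values come from
# stats::fisher.test / stats::wilcox.test (two-sided Fisher extremeness is
# probability-based there, the convention adopted here); what this module
# adds is the reporting contract: the sample odds ratio (a*d)/(b*c) rather
# than fisher.test's conditional MLE, explicit exactness thresholds, and a
# uniform result structure.

.newTestResult <- function(method, alternative, statistic, p.value,
                           odds.ratio = NA_real_, conf.int = NULL,
                           table = NULL) {
  structure(list(method = method, alternative = alternative,
                 statistic = statistic, p.value = p.value,
                 odds.ratio = odds.ratio, conf.int = conf.int,
                 table = table),
            class = "erbsTest")
}

#' @export
print.erbsTest <- function(x, ...) {
  cat(x$method, sprintf("(%s)\n", x$alternative))
  if (!is.na(x$statistic)) cat("  statistic =", format(x$statistic), "\n")
  cat("  p-value  =", format(x$p.value), "\n")
  if (!is.null(x$odds.ratio) && !all(is.na(x$odds.ratio)))
    cat("  odds ratio =", format(x$odds.ratio), "\n")
  if (!is.null(x$conf.int))
    cat("  95% CI   = [", format(x$conf.int[1]), ",",
        format(x$conf.int[2]), "]\n")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of tables with
#' the same margins that are as or more extreme (two-sided extremeness is
#' probability-based: tables whose probability does not exceed the
#' observed one).  The reported odds ratio is the sample estimate
#' `(a*d)/(b*c)` -- `Inf` when `b*c = 0` with `a*d > 0`, `NA` when a table
#' margin is zero -- not the conditional MLE; the confidence interval is
#' the one from the exact conditional test.
#'
#' @param a,b,c,d cell counts (row = group membership, column = feature
#'   presence), or pass a 2x2 matrix as `a`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `erbsTest` result list with `p.value`, `odds.ratio`,
#'   `conf.int` and the input `table`.
#' @export
#' @examples
#' fisherExactTest(5, 0, 0, 5)$p.value   # 2 / choose(10, 5)
fisherExactTest <- function(a, b = NULL, c = NULL, d = NULL,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2L)  # byrow: (a b / c d)
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != floor(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  ft <- fisher.test(tab, alternative = alternative)
  ad <- tab[1, 1] * tab[2, 2]
  bc <- tab[1, 2] * tab[2, 1]
  or <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    NA_real_
  } else if (bc == 0) {
    Inf
  } else {
    ad / bc
  }
  ci <- if (!is.null(ft$conf.int)) as.numeric(ft$conf.int) else NULL
  .newTestResult("Fisher's exact test", alternative,
                 statistic = NA_real_, p.value = ft$p.value,
                 odds.ratio = or, conf.int = ci, table = tab)
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' The unpaired rank test for two independent groups -- the pipeline
#' default for comparing fold-change distributions between gene groups.
#' Midranks are used for ties; the p-value is exact (enumeration over
#' assignments) when the pooled sample size is at most `exactLimit` and
#' there are no ties, and otherwise uses the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric value groups, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exactLimit pooled-size threshold for the exact p-value
#'   (default 12).
#' @return An `erbsTest` result list (statistic = Mann-Whitney U for `x`).
#' @export
wilcoxonRankSumTest <- function(x, y,
                                alternative = c("two.sided", "greater", "less"),
                                exactLimit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exactLimit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied pooled sample: no evidence either way
  .newTestResult(
    if (exact) "Wilcoxon rank-sum test (exact)"
    else "Wilcoxon rank-sum test (normal approximation)",
    alternative, statistic = unname(wt$statistic), p.value = p)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (an all-zero input is an error); tied
#' magnitudes receive midranks.  The p-value is exact when at most
#' `exactLimit` nonzero differences remain and magnitudes are untied,
#' otherwise the normal approximation with continuity correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exactLimit sample-size threshold for the exact p-value
#'   (default 15).
#' @return An `erbsTest` result list (statistic = V, the positive-rank
#'   sum).
#' @export
#' @examples
#' wilcoxonSignedRankTest(c(1, 2, 3), alternative = "greater")$p.value  # 1/8
wilcoxonSignedRankTest <- function(diffs,
                                   alternative = c("two.sided", "greater", "less"),
                                   exactLimit = 15L) {
  alternative <- match.arg(alternative)
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L)
    stop("all differences are zero; the signed-rank test is undefined")
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= exactLimit && !ties
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = alternative, exact = exact,
                correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  .newTestResult(
    if (exact) "Wilcoxon signed-rank test (exact)"
    else "Wilcoxon signed-rank test (normal approximation)",
    alternative, statistic = unname(wt$statistic), p.value = p)
}
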