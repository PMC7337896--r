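# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards, so that seeded operations never perturb
#' the surrounding random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Random DNA string
#'
#' Uniform i.i.d. nucleotides over A, C, G, T; draws from the current RNG
#' stream.  Uses a raw-byte lookup so that multi-megabase chromosomes are
#' cheap to build.
#'
#' @param n length in bases.
#' @return A single character string of length `n`.
#' @keywords internal
#' @noRd
randomDNA <- function(n) {
  if (n == 0L) return("")
  idx <- sample.int(4L, n, replace = TRUE)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])  # A C G T
}

# Validate a character scalar DNA sequence over {A,C,G,T,N}; returns the
# uppercased sequence or errors.
.checkDNA <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'", what, "' must be a single character string")
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("'", what, "' contains characters outside {A,C,G,T,N}")
  seq
}

# Label used in error messages for the i-th range of a GRanges.
.rangeLabel <- function(gr, i) {
  nm <- names(gr)
  if (!is.null(nm) && !is.na(nm[i]) && nzchar(nm[i])) nm[i]
  else sprintf("%s:%d-%d", as.character(seqnames(gr)[i]),
               start(gr)[i] - 1L, end(gr)[i])
}
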