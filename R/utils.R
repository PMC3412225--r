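#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded to
#' \code{seed}, then restores the previous RNG state, so that seeded
#' generators are deterministic without disturbing the caller's stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Round to a number of significant figures
#'
#' Thin wrapper around \code{\link[base]{signif}}, exported so reported
#' headline numbers can be rounded with the same convention everywhere.
#' Rounding is presentation-only and is never applied inside computations.
#'
#' @param x numeric.
#' @param n number of significant figures (>= 1).
#' @return rounded numeric.
#' @examples
#' toSigFigs(12089.3, 2)  # 12000
#' @export
toSigFigs <- function(x, n) {
  stopifnot(n >= 1)
  signif(x, n)
}

#' Floor to a multiple of a step
#'
#' @param x numeric.
#' @param step positive step size.
#' @return largest multiple of \code{step} not exceeding \code{x}.
#' @examples
#' floorToNearest(406, 100)  # 400
#' @export
floorToNearest <- function(x, step) {
  stopifnot(step > 0)
  floor(x / step) * step
}

#' Round to the nearest power of ten
#'
#' Order-of-magnitude reporting for molecule counts.
#'
#' @param x positive numeric.
#' @return 10^round(log10(x)).
#' @examples
#' nearestPowerOfTen(1.06e11)  # 1e11
#' @export
nearestPowerOfTen <- function(x) {
  stopifnot(all(x > 0))
  10^round(log10(x))
}

## coerce character / DNAString to DNAString, validating the alphabet
.asDNA <- function(x, what = "sequence") {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  if (is.character(x) && length(x) == 1L) {
    bad <- gsub("[ACGTN]", "", toupper(x))
    if (nchar(bad) > 0L)
      stop(what, " contains characters outside {A,C,G,T,N}: ",
           paste(unique(strsplit(bad, "")[[1L]]), collapse = ","))
    return(Biostrings::DNAString(toupper(x)))
  }
  stop(what, " must be a DNAString or a single character string")
}

## i.i.d. random DNA at a given GC fraction (caller handles seeding)
.randomDNA <- function(n, gc = 0.42) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Biostrings::DNAString(paste(
    sample(names(p), n, replace = TRUE, prob = p), collapse = ""))
}

## A+T fraction of a character/DNAString window
.atFraction <- function(x) {
  x <- .asDNA(x)
  if (length(x) == 0L) return(NA_real_)
  sum(Biostrings::letterFrequency(x, c("A", "T"))) / length(x)
}

## 1-based closed IRanges -> 0-based half-open list for JSON
.iranges0 <- function(r) {
  if (length(r) == 0L) return(NULL)
  list(start = start(r) - 1L, end = end(r))
}
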