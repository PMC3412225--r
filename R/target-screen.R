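## Target-locus suitability screening: probe cross-hybridization scan,
## endonuclease-site census, and repeat-free primer windows.

#' Scan a target for probe-oligo matches
#'
#' Gapless (Hamming) scan of every window on both strands against each
#' oligo, reporting windows within \code{maxMismatch} substitutions.  A
#' plus-strand hit is a window equal to the oligo; a minus-strand hit is
#' a window equal to its reverse complement (target amplicons are
#' double-stranded, so both strands can cross-hybridize).  Ambiguous
#' bases (N) count as mismatches.
#'
#' @param target target sequence (DNAString or character).
#' @param oligos \link[Biostrings]{DNAStringSet} of probe oligos.
#' @param maxMismatch mismatch cap (default 3, the "three or fewer
#'   mismatches" exclusion rule).
#' @return data.frame sorted by position: \code{oligoId},
#'   \code{position} (0-based window start on the target),
#'   \code{strand}, \code{mismatches}.
#' @examples
#' scanOligos("ACGTACGTACGT", Biostrings::DNAStringSet(c(o1 = "GTAC")),
#'            maxMismatch = 0)
#' @export
scanOligos <- function(target, oligos, maxMismatch = 3) {
  target <- .asDNA(target, "target")
  if (is.character(oligos)) oligos <- Biostrings::DNAStringSet(oligos)
  stopifnot(is(oligos, "DNAStringSet"), maxMismatch >= 0)
  ids <- if (is.null(names(oligos))) paste0("oligo", seq_along(oligos))
         else names(oligos)
  rows <- list()
  for (i in seq_along(oligos)) {
    olig <- oligos[[i]]
    if (length(olig) >= length(target))
      stop("oligo '", ids[i], "' is not shorter than the target")
    for (str in c("+", "-")) {
      pat <- if (str == "+") olig else reverseComplement(olig)
      hits <- Biostrings::matchPattern(pat, target,
                                       max.mismatch = maxMismatch,
                                       with.indels = FALSE, fixed = TRUE)
      if (length(hits) == 0L) next
      mm <- vapply(seq_along(hits), function(j)
        Biostrings::neditAt(pat, target, at = start(hits)[j],
                            with.indels = FALSE, fixed = TRUE),
        integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        oligoId = ids[i], position = start(hits) - 1L, strand = str,
        mismatches = mm)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(oligoId = character(), position = integer(),
                         strand = character(), mismatches = integer())
  out[order(out$position, out$oligoId, out$strand), , drop = FALSE]
}

#' Census of L1 endonuclease sites
#'
#' Finds exact occurrences of the endonuclease nick consensus on the
#' plus strand, and of its reverse complement (minus-strand sites).
#'
#' @param target target sequence.
#' @param motif nick consensus (default \code{"TTAAAA"}).
#' @return data.frame sorted by position (\code{position} 0-based,
#'   \code{strand}); attribute \code{density} holds sites per kb.
#' @examples
#' countEnSites("GGTTAAAAGG")  # one plus-strand site at position 2
#' @export
countEnSites <- function(target, motif = "TTAAAA") {
  target <- .asDNA(target, "target")
  stopifnot(nchar(motif) >= 4)
  rc <- as.character(reverseComplement(Biostrings::DNAString(motif)))
  plus <- start(Biostrings::matchPattern(motif, target)) - 1L
  minus <- start(Biostrings::matchPattern(rc, target)) - 1L
  out <- data.frame(
    position = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus))))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "density") <- nrow(out) / (length(target) / 1000)
  out
}

#' Repeat-free windows for primer design
#'
#' Complements the (merged) union of repeat intervals within the target
#' and keeps the maximal repeat-free intervals long enough for primer
#' design.  Overlapping repeat intervals are merged, not rejected.
#'
#' @param targetLength target length, bp.
#' @param repeatIntervals repeat annotation: an \link[IRanges]{IRanges}
#'   (1-based) or a data.frame with 0-based half-open \code{start},
#'   \code{end} columns (BED convention).
#' @param minWindow minimum window length, bp.
#' @return \link[IRanges]{IRanges} of windows (1-based), disjoint and
#'   sorted.
#' @examples
#' primerWindows(1000, data.frame(start = c(100, 150), end = c(200, 300)),
#'               minWindow = 50)  # [1,100] and [301,1000] 1-based
#' @export
primerWindows <- function(targetLength, repeatIntervals = NULL,
                          minWindow = 200) {
  stopifnot(targetLength >= 1, minWindow >= 1)
  rep1 <- if (is.null(repeatIntervals)) IRanges::IRanges()
    else if (is(repeatIntervals, "IRanges")) repeatIntervals
    else IRanges::IRanges(start = repeatIntervals$start + 1L,
                          end = repeatIntervals$end)
  if (length(rep1) && (min(start(rep1)) < 1L || max(end(rep1)) > targetLength))
    stop("repeat intervals outside [0, targetLength)")
  free <- IRanges::gaps(IRanges::reduce(rep1), start = 1L,
                        end = targetLength)
  free[width(free) >= minWindow]
}

#' Screen one target locus
#'
#' Applies the three suitability criteria: no probe-oligo match within
#' the mismatch cap (so the locus cannot be captured without an
#' insertion), presence and density of endonuclease sites (amenability
#' to L1 integration), and repeat-free windows for nested primer design.
#'
#' @inheritParams scanOligos
#' @param repeatIntervals repeat annotation for
#'   \code{\link{primerWindows}} (NULL = no repeats).
#' @param motif endonuclease motif.
#' @param minWindow minimum primer window, bp.
#' @param targetId identifier for the report.
#' @return a \linkS4class{ScreenReport}.
#' @export
screenTarget <- function(target, oligos, repeatIntervals = NULL,
                         maxMismatch = 3, motif = "TTAAAA",
                         minWindow = 200, targetId = "target") {
  target <- .asDNA(target, "target")
  hits <- scanOligos(target, oligos, maxMismatch)
  en <- countEnSites(target, motif)
  new("ScreenReport", targetId = targetId, oligoHits = hits,
      passesOligoScreen = nrow(hits) == 0L, enSites = en,
      enDensity = attr(en, "density"),
      primerWindows = primerWindows(length(target), repeatIntervals,
                                    minWindow))
}
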