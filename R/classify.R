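## Structural classification of candidate amplicons: genuine TPRT
## insertion vs PCR template-switch chimera vs no insertion.
##
## A genuine de novo insertion must carry an L1 segment and a poly-A
## tail flanked 5' and 3' by collinear target sequences; a target site
## duplication is recorded when found but not required.  Chimeras carry
## an L1 segment but lack one concordant flank, with the discordance
## junction typically falling in an A/T-rich tract.

#' Classifier thresholds
#'
#' Alignment scoring is local dynamic programming with match +1,
#' mismatch -1, gap open 2, gap extend 1.  Flanks must align at >= 0.90
#' identity over >= 50 nt, the element at >= 0.85 identity over
#' >= 100 nt (older, diverged L1 copies still match at this level).
#' Poly-A calls need >= 10 nt at >= 0.8 A fraction starting within
#' 10 bp of the element 3' end; TSDs are exact repeats of 4-30 nt; the
#' junction composition window is 20 nt with an A/T-rich call at 0.70.
#'
#' @param ... named overrides of the defaults listed above.
#' @return named list of thresholds.
#' @export
classifierThresholds <- function(...) {
  th <- list(match = 1, mismatch = -1, gapOpening = 2, gapExtension = 1,
             flankIdentity = 0.90, flankMinLen = 50,
             l1Identity = 0.85, l1MinLen = 100,
             polyAMinLen = 10, polyAPurity = 0.8, polyAAnchorSlack = 10,
             tsdMinLen = 4, tsdMaxLen = 30,
             junctionWindow = 20, junctionATMin = 0.70)
  extra <- list(...)
  bad <- setdiff(names(extra), names(th))
  if (length(bad)) stop("unknown thresholds: ", paste(bad, collapse = ", "))
  th[names(extra)] <- extra
  th
}

## local alignment wrapper; returns NULL or a coordinate/identity record
.swLocal <- function(pattern, subject, th) {
  if (length(pattern) == 0L || length(subject) == 0L) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = th$match, mismatch = th$mismatch, baseOnly = FALSE)
  a <- Biostrings::pairwiseAlignment(
    pattern, subject, type = "local", substitutionMatrix = mat,
    gapOpening = th$gapOpening, gapExtension = th$gapExtension)
  pr <- Biostrings::pattern(a); sr <- Biostrings::subject(a)
  list(score = Biostrings::score(a),
       patStart = start(pr), patEnd = end(pr),
       subStart = start(sr), subEnd = end(sr),
       identity = Biostrings::nmatch(a) / nchar(a),
       aln = a)
}

## length of the maximal-scoring "noisy" end of an alignment-column
## quality vector (TRUE = match): trims ends whose local mismatch/gap
## density exceeds ~30%, the signature of chance extension through
## A-rich micro-homology at insertion junctions
.noisyEndLen <- function(good) {
  sc <- 0; best <- 0; cut <- 0L
  for (i in seq_along(good)) {
    sc <- sc + if (good[i]) -0.3 else 0.7
    if (sc > best) { best <- sc; cut <- i }
    if (sc < best - 30) break
  }
  cut
}

## decompose a local alignment into clean collinear segments:
## split at gap runs >= splitMin (an amplicon insert bridged by the
## aligner), then trim noisy segment ends; coordinates are absolute on
## pattern and subject
.swSegments <- function(pattern, subject, th, splitMin = 40L) {
  rec <- .swLocal(pattern, subject, th)
  if (is.null(rec)) return(list())
  a <- rec$aln
  pch <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1L]]
  sch <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1L]]
  ncol <- length(pch)
  good <- pch == sch & pch != "-"
  gapRun <- function(isGap) {
    r <- rle(isGap)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values & r$lengths >= splitMin
    IRanges::IRanges(s[keep], e[keep])
  }
  cuts <- c(gapRun(pch == "-"), gapRun(sch == "-"))
  segs <- IRanges::gaps(IRanges::reduce(cuts), start = 1L, end = ncol)
  patPos <- cumsum(pch != "-") + rec$patStart - 1L   # pattern coord per col
  subPos <- cumsum(sch != "-") + rec$subStart - 1L
  out <- list()
  for (i in seq_along(segs)) {
    c1 <- start(segs)[i]; c2 <- end(segs)[i]
    g <- good[c1:c2]
    lt <- .noisyEndLen(g)
    rt <- .noisyEndLen(rev(g))
    c1t <- c1 + lt; c2t <- c2 - rt
    if (c2t - c1t + 1L < 2L) next
    gseg <- good[c1t:c2t]
    if (!any(gseg)) next
    ## snap segment ends onto match columns
    c1t <- c1t + which(gseg)[1L] - 1L
    c2t <- c2t - (length(gseg) - max(which(gseg)))
    out[[length(out) + 1L]] <- list(
      patStart = patPos[c1t] - (pch[c1t] == "-"),
      patEnd = patPos[c2t],
      subStart = subPos[c1t] - (sch[c1t] == "-"),
      subEnd = subPos[c2t],
      identity = sum(good[c1t:c2t]) / (c2t - c1t + 1L),
      score = rec$score)
  }
  out
}

.flankOK <- function(a, th)
  !is.null(a) && a$identity >= th$flankIdentity &&
    (a$patEnd - a$patStart + 1L) >= th$flankMinLen

#' Align amplicon ends to the target reference
#'
#' Finds the best local alignment of the amplicon to the target, then
#' aligns the remaining end of the amplicon separately, yielding the 5'
#' and 3' target flanks.  Flanks below the identity/length thresholds
#' are reported absent.  An amplicon that aligns to the target over
#' (nearly) its whole length is flagged \code{fullMatch}: it
#' reconstructs the target with no internal insertion.
#'
#' @param amplicon candidate amplicon sequence.
#' @param targetRef target locus reference sequence (>= 500 bp).
#' @param thresholds see \code{\link{classifierThresholds}}.
#' @return list with \code{flank5}, \code{flank3} (each NULL or a list
#'   with \code{amp} and \code{target} \link[IRanges]{IRanges} plus
#'   \code{identity}) and \code{fullMatch}.
#' @export
alignFlanks <- function(amplicon, targetRef,
                        thresholds = classifierThresholds()) {
  amplicon <- .asDNA(amplicon, "amplicon")
  targetRef <- .asDNA(targetRef, "targetRef")
  if (length(targetRef) < 500) stop("targetRef must be >= 500 bp")
  th <- thresholds
  len <- length(amplicon)
  none <- list(flank5 = NULL, flank3 = NULL, fullMatch = FALSE)
  segs <- Filter(function(s) .flankOK(s, th),
                 .swSegments(amplicon, targetRef, th))
  if (length(segs) == 0L) return(none)
  mk <- function(a, off = 0L) list(
    amp = IRanges::IRanges(a$patStart + off, a$patEnd + off),
    target = IRanges::IRanges(a$subStart, a$subEnd),
    identity = a$identity)
  if (length(segs) == 1L &&
      (segs[[1L]]$patEnd - segs[[1L]]$patStart + 1L) >= 0.9 * len)
    return(list(flank5 = mk(segs[[1L]]), flank3 = NULL, fullMatch = TRUE))
  if (length(segs) >= 2L) {
    ## the aligner bridged the insert: leftmost and rightmost clean
    ## segments are the two flanks
    ord <- order(vapply(segs, `[[`, numeric(1), "patStart"))
    return(list(flank5 = mk(segs[[ord[1L]]]),
                flank3 = mk(segs[[ord[length(ord)]]]), fullMatch = FALSE))
  }
  a1 <- segs[[1L]]
  leftGap <- a1$patStart - 1L
  rightGap <- len - a1$patEnd
  flank5 <- flank3 <- NULL
  secondBest <- function(from, to, off) {
    s2 <- Filter(function(s) .flankOK(s, th),
                 .swSegments(subseq(amplicon, from, to), targetRef, th))
    if (length(s2) == 0L) return(NULL)
    nm <- vapply(s2, function(s)
      (s$patEnd - s$patStart + 1L) * s$identity, numeric(1))
    mk(s2[[which.max(nm)]], off = off)
  }
  if (leftGap <= rightGap) {       # a1 sits toward the amplicon start
    flank5 <- mk(a1)
    if (rightGap >= th$flankMinLen)
      flank3 <- secondBest(a1$patEnd + 1L, len, a1$patEnd)
  } else {
    flank3 <- mk(a1)
    if (leftGap >= th$flankMinLen)
      flank5 <- secondBest(1L, a1$patStart - 1L, 0L)
  }
  list(flank5 = flank5, flank3 = flank3, fullMatch = FALSE)
}

#' Locate the L1 segment of an amplicon
#'
#' Best local alignment of the amplicon against the element reference on
#' either strand.  Reports the amplicon span, orientation relative to
#' the amplicon plus strand, and the 5'-truncation offset (distance from
#' the element 5' end to the alignment start on the reference); returns
#' NULL below the identity or length threshold.
#'
#' @param amplicon candidate amplicon sequence.
#' @param l1Ref element reference sequence (>= 2000 bp).
#' @param thresholds see \code{\link{classifierThresholds}}.
#' @return NULL, or list with \code{amp} (IRanges), \code{orientation},
#'   \code{truncationOffset} (0-based bp), \code{identity}.
#' @export
locateL1 <- function(amplicon, l1Ref, thresholds = classifierThresholds()) {
  amplicon <- .asDNA(amplicon, "amplicon")
  l1Ref <- .asDNA(l1Ref, "l1Ref")
  if (length(l1Ref) < 2000) stop("l1Ref must be >= 2000 bp")
  th <- thresholds
  len <- length(amplicon)
  best <- NULL; bestMatches <- -Inf
  for (orientation in c("plus", "minus")) {
    pat <- if (orientation == "plus") amplicon
           else reverseComplement(amplicon)
    for (a in .swSegments(pat, l1Ref, th)) {
      w <- a$patEnd - a$patStart + 1L
      if (a$identity < th$l1Identity || w < th$l1MinLen) next
      if (w * a$identity <= bestMatches) next
      bestMatches <- w * a$identity
      amp <- if (orientation == "plus")
        IRanges::IRanges(a$patStart, a$patEnd)
      else IRanges::IRanges(len - a$patEnd + 1L, len - a$patStart + 1L)
      best <- list(amp = amp, orientation = orientation,
                   truncationOffset = a$subStart - 1L,
                   identity = a$identity)
    }
  }
  best
}

#' Find the poly-A (or poly-T) tract at an element junction
#'
#' Searches for the longest window that starts within
#' \code{polyAAnchorSlack} bases of the anchor and keeps the A fraction
#' at or above the purity threshold.  For minus-orientation insertions
#' the tail appears as a T tract 5' of the element segment, searched
#' leftward from the anchor.
#'
#' @param amplicon amplicon sequence.
#' @param anchor 1-based coordinate the tract must start at (plus) or
#'   end at (minus): one base past the element 3' end.
#' @param orientation \code{"plus"} (A tract rightward) or
#'   \code{"minus"} (T tract leftward).
#' @param thresholds see \code{\link{classifierThresholds}}.
#' @return NULL, or list with \code{range} (IRanges) and \code{purity}.
#' @export
findPolyA <- function(amplicon, anchor, orientation = "plus",
                      thresholds = classifierThresholds()) {
  amplicon <- .asDNA(amplicon, "amplicon")
  th <- thresholds
  len <- length(amplicon)
  if (anchor < 1L || anchor > len) stop("anchor outside the amplicon")
  base <- if (orientation == "plus") "A" else "T"
  chars <- strsplit(as.character(amplicon), "")[[1L]]
  hit <- chars == base
  slack <- th$polyAAnchorSlack
  best <- NULL
  ## run extension scored +1 per matching base, -3 per other base,
  ## endpoints anchored on matching bases; the best-scoring extension is
  ## the tract itself rather than a maximally diluted window
  bestSc <- -Inf
  for (s in max(1L, anchor - slack):min(len, anchor + slack)) {
    if (!hit[s]) next
    limit <- if (orientation == "plus") min(len, s + 500L) else max(1L, s - 500L)
    sc <- 0; scBest <- -Inf; endBest <- NA_integer_
    for (pos in seq(s, limit, by = if (orientation == "plus") 1L else -1L)) {
      sc <- sc + if (hit[pos]) 1 else -3
      if (hit[pos] && sc > scBest) { scBest <- sc; endBest <- pos }
      if (sc < scBest - 30) break
    }
    if (is.na(endBest)) next
    rng <- IRanges::IRanges(min(s, endBest), max(s, endBest))
    pur <- sum(hit[start(rng):end(rng)]) / width(rng)
    if (width(rng) >= th$polyAMinLen && pur >= th$polyAPurity &&
        (scBest > bestSc ||
         (scBest == bestSc && width(rng) > width(best$range)))) {
      bestSc <- scBest
      best <- list(range = rng, purity = pur)
    }
  }
  best
}

#' Find a target site duplication
#'
#' TPRT duplicates the target bases between the two nicks, so on the
#' amplicon the duplicated tract appears at the end of the 5' flank and
#' again at the start of the 3' flank, while on the target reference the
#' two flank projections overlap over exactly that tract.  The TSD is
#' therefore the target segment between \code{rightBreak} and
#' \code{leftBreak}: present when the flanks overlap by at least
#' \code{minLen} bases, absent for blunt insertions (no overlap) and for
#' chimeras (breaks on different molecules; no consistent overlap).
#'
#' @param targetRef target reference sequence.
#' @param leftBreak 1-based target coordinate of the last base of the 5'
#'   flank.
#' @param rightBreak 1-based target coordinate of the first base of the
#'   3' flank.
#' @param maxLen longest duplication reported (longer overlaps are
#'   truncated; the classifier treats them as discordant anyway).
#' @param minLen shortest duplication reported.
#' @return NULL, or list with \code{sequence} and \code{length}.
#' @examples
#' findTSD("GGGGACGTACGTGGGG", leftBreak = 12, rightBreak = 5)  # ACGTACGT
#' @export
findTSD <- function(targetRef, leftBreak, rightBreak, maxLen = 30,
                    minLen = 4) {
  targetRef <- .asDNA(targetRef, "targetRef")
  n <- length(targetRef)
  stopifnot(leftBreak >= 1, leftBreak <= n, rightBreak >= 1, rightBreak <= n)
  overlap <- leftBreak - rightBreak + 1L
  if (overlap < minLen) return(NULL)
  k <- as.integer(min(overlap, maxLen))
  list(sequence = as.character(subseq(targetRef, leftBreak - k + 1L,
                                      leftBreak)),
       length = k)
}

#' A+T fraction around a position
#'
#' Fraction of A or T bases in a window centred at \code{position},
#' clipped at the sequence ends.
#'
#' @param sequence DNA sequence.
#' @param position 1-based centre coordinate.
#' @param window window width, nt.
#' @return A+T fraction in [0,1].
#' @export
junctionComposition <- function(sequence, position, window = 20) {
  x <- .asDNA(sequence, "sequence")
  stopifnot(position >= 1, position <= length(x), window >= 1)
  half <- window %/% 2L
  s <- max(1L, position - half)
  e <- min(length(x), s + window - 1L)
  .atFraction(subseq(x, s, e))
}

## refine a raw junction coordinate to the most A/T-rich nearby position,
## mirroring manual annotation of template-switch points to the A-rich
## linker they fall in
.refineJunction <- function(amplicon, raw, th) {
  len <- length(amplicon)
  cand <- max(1L, raw - 10L):min(len, raw + 10L)
  at <- vapply(cand, function(p)
    junctionComposition(amplicon, p, th$junctionWindow), numeric(1))
  best <- cand[which.max(at)]
  list(position = best, at = max(at))
}

#' Classify a candidate amplicon
#'
#' Applies the verdict rules of the screen: \code{"genuine"} if both
#' target flanks are present and collinear on the target, an element
#' segment is present, and a poly-A tract sits at the element 3' end
#' (TSD recorded if found, flagged but not required);
#' \code{"no_insertion"} if the amplicon reconstructs target sequence
#' with no element segment; \code{"chimera"} if an element segment is
#' present but a flank is absent or discordant, in which case the
#' discordance junction is located, refined to the most A/T-rich nearby
#' position, and its composition recorded; \code{"unresolved"}
#' otherwise.  The evidence slot lists which criteria passed or failed.
#'
#' @param amplicon candidate amplicon (DNAString or character; alphabet
#'   A,C,G,T,N; length >= 100).
#' @param targetRef target locus reference.
#' @param l1Ref element reference.
#' @param thresholds see \code{\link{classifierThresholds}}.
#' @param id amplicon identifier for the report.
#' @return an \linkS4class{InsertionAnnotation}.
#' @examples
#' cfg <- simConfig(seed = 11, l1Length = 2000, targetLength = 1200,
#'                  truncationOffset = 500)
#' tl <- genTargetLocus(1200, plantedEnSites = 3, seed = 11)
#' l1 <- genL1Reference(cfg)
#' amp <- genInsertionAmplicon(tl, l1, cfg)
#' verdict(classifyAmplicon(amp$sequence, tl$sequence, l1))  # "genuine"
#' @export
classifyAmplicon <- function(amplicon, targetRef, l1Ref,
                             thresholds = classifierThresholds(),
                             id = "amplicon") {
  amplicon <- .asDNA(amplicon, "amplicon")
  if (length(amplicon) < 100) stop("amplicon must be >= 100 bp")
  targetRef <- .asDNA(targetRef, "targetRef")
  l1Ref <- .asDNA(l1Ref, "l1Ref")
  th <- thresholds
  ev <- character()

  l1 <- locateL1(amplicon, l1Ref, th)
  fl <- alignFlanks(amplicon, targetRef, th)
  ev <- c(ev,
    if (is.null(l1)) "L1 segment: absent"
    else sprintf("L1 segment: present (%s strand, 5' truncation %d bp, identity %.2f)",
                 l1$orientation, l1$truncationOffset, l1$identity),
    if (is.null(fl$flank5)) "5' target flank: absent"
    else sprintf("5' target flank: present (identity %.2f)",
                 fl$flank5$identity),
    if (is.null(fl$flank3)) "3' target flank: absent"
    else sprintf("3' target flank: present (identity %.2f)",
                 fl$flank3$identity))

  emptyAnn <- function(verdict, extra = character(), polyA = NULL,
                       tsd = NA_character_, junction = NA_integer_,
                       junctionAT = NA_real_) {
    new("InsertionAnnotation", id = id, verdict = verdict,
        flank5 = if (is.null(fl$flank5)) IRanges::IRanges()
                 else fl$flank5$amp,
        flank5Target = if (is.null(fl$flank5)) IRanges::IRanges()
                       else fl$flank5$target,
        flank5Identity = if (is.null(fl$flank5)) NA_real_
                         else fl$flank5$identity,
        flank3 = if (is.null(fl$flank3)) IRanges::IRanges()
                 else fl$flank3$amp,
        flank3Target = if (is.null(fl$flank3)) IRanges::IRanges()
                       else fl$flank3$target,
        flank3Identity = if (is.null(fl$flank3)) NA_real_
                         else fl$flank3$identity,
        l1Segment = if (is.null(l1)) IRanges::IRanges() else l1$amp,
        l1Orientation = if (is.null(l1)) NA_character_ else l1$orientation,
        l1TruncationOffset = if (is.null(l1)) NA_real_
                             else as.numeric(l1$truncationOffset),
        polyA = if (is.null(polyA)) IRanges::IRanges() else polyA$range,
        polyAPurity = if (is.null(polyA)) NA_real_ else polyA$purity,
        tsd = tsd, junctionPosition = junction,
        junctionATFraction = junctionAT,
        evidence = c(ev, extra))
  }

  if (is.null(l1)) {
    if (fl$fullMatch || !is.null(fl$flank5) || !is.null(fl$flank3))
      return(emptyAnn("no_insertion",
                      "verdict: target sequence with no L1 segment"))
    return(emptyAnn("unresolved",
                    "verdict: no L1 segment and no target flank"))
  }

  ## poly-A at the element 3' end (T tract 5' of a minus-strand element)
  anchor <- if (l1$orientation == "plus")
    min(length(amplicon), end(l1$amp) + 1L) else max(1L, start(l1$amp) - 1L)
  polyA <- findPolyA(amplicon, anchor, l1$orientation, th)
  ev <- c(ev, if (is.null(polyA)) "poly-A tail: absent"
          else sprintf("poly-A tail: %d nt at purity %.2f",
                       width(polyA$range), polyA$purity))

  both <- !is.null(fl$flank5) && !is.null(fl$flank3)
  if (both) {
    ## collinear flanks: 5' before 3' on the amplicon with room for the
    ## insert between them, and target projections meeting at the
    ## insertion point (their overlap is the TSD, allowing alignment
    ## slack in A-rich junctions)
    overlap <- end(fl$flank5$target) - start(fl$flank3$target) + 1L
    gapBetween <- start(fl$flank3$amp) - end(fl$flank5$amp) - 1L
    ordered <- start(fl$flank5$amp) < start(fl$flank3$amp) &&
      gapBetween >= th$l1MinLen
    collinear <- ordered && overlap >= -20L && overlap <= th$tsdMaxLen + 20L
    if (collinear && !is.null(polyA)) {
      ## flank alignments can overrun into the poly-A (its A's match
      ## target A's); trim the overrun before measuring the overlap
      leftBreak <- end(fl$flank5$target)
      rightBreak <- start(fl$flank3$target)
      if (l1$orientation == "plus") {
        over <- end(polyA$range) - start(fl$flank3$amp) + 1L
        if (over > 0L) rightBreak <- rightBreak + over
      } else {
        over <- end(fl$flank5$amp) - start(polyA$range) + 1L
        if (over > 0L) leftBreak <- leftBreak - over
      }
      leftBreak <- max(1L, min(leftBreak, length(targetRef)))
      rightBreak <- max(1L, min(rightBreak, length(targetRef)))
      tsd <- findTSD(targetRef, leftBreak, rightBreak,
                     maxLen = th$tsdMaxLen, minLen = th$tsdMinLen)
      ev2 <- c("flanks collinear at the insertion point",
               if (is.null(tsd))
                 "TSD: none found (recorded only; not required)"
               else sprintf("TSD: %d nt (%s)", tsd$length, tsd$sequence),
               "verdict: structure of a genuine TPRT insertion")
      return(emptyAnn("genuine", ev2, polyA = polyA,
                      tsd = if (is.null(tsd)) NA_character_
                            else tsd$sequence))
    }
    if (!collinear) {
      j <- .refineJunction(amplicon, end(fl$flank5$amp), th)
      return(emptyAnn("chimera",
        c("flanks discordant on the target",
          sprintf("junction A+T fraction %.2f", j$at),
          "verdict: PCR template-switch chimera"),
        polyA = polyA, junction = j$position - 1L, junctionAT = j$at))
    }
    return(emptyAnn("unresolved",
      "collinear flanks and L1 segment but no poly-A tail",
      polyA = polyA))
  }

  if (!is.null(fl$flank5) || !is.null(fl$flank3)) {
    raw <- if (!is.null(fl$flank5)) end(fl$flank5$amp)
           else start(fl$flank3$amp)
    j <- .refineJunction(amplicon, raw, th)
    return(emptyAnn("chimera",
      c("single target flank with an L1 segment",
        sprintf("junction A+T fraction %.2f", j$at),
        "verdict: PCR template-switch chimera"),
      polyA = polyA, junction = j$position - 1L, junctionAT = j$at))
  }
  emptyAnn("unresolved", "L1 segment without any target flank",
           polyA = polyA)
}
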