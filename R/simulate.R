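## Synthetic-data generator: seeded stand-ins for every input of the
## pipeline, with ground truth for round-trip testing.  Backgrounds are
## i.i.d. nucleotides at the requested GC fraction; simulated elements
## are A/T rich like real L1s.

## derive a per-generator seed from the user seed and a tag, < 2^31
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Simulated L1 reference element
#'
#' Generates an element of \code{l1Length} bases at the configured
#' (A/T-rich) composition.  Probe oligos for hybridization capture are
#' taken from its 3'-terminal 1.5 kb by \code{\link{genBioOligos}}, so
#' that 5'-truncated insertions remain recoverable.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \link[Biostrings]{DNAString} of length \code{l1Length};
#'   byte-identical under a fixed seed.
#' @examples
#' l1 <- genL1Reference(simConfig(seed = 1))
#' @export
genL1Reference <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  if (config@l1Length < 2000L) stop("l1Length must be >= 2000 bp")
  withSeed(.deriveSeed(config@seed, "l1"),
           .randomDNA(config@l1Length, config@l1GcFraction))
}

#' Biotinylated probe oligos against the L1 3' terminus
#'
#' Returns \code{n} oligos that are exact reverse complements of
#' distinct, evenly spaced windows inside the 3'-terminal 1500 nt of the
#' element, mimicking an equimolar capture-oligo mixture targeting the
#' most conserved 3' sequences.
#'
#' @param l1Ref the element sequence.
#' @param n number of oligos (default 4).
#' @param length oligo length, nt (<= 1500).
#' @return a \link[Biostrings]{DNAStringSet}; \code{mcols()$l1Start}
#'   holds the 1-based window start on the element.
#' @examples
#' oligos <- genBioOligos(genL1Reference(), n = 4, length = 30)
#' @export
genBioOligos <- function(l1Ref, n = 4, length = 30) {
  l1Ref <- .asDNA(l1Ref, "l1Ref")
  stopifnot(n >= 1, length >= 1)
  if (length > 1500) stop("oligo length exceeds the 1500-nt 3' window")
  L <- length(l1Ref)
  first <- L - 1500L + 1L
  last <- L - length + 1L
  if (n > last - first + 1L) stop("windows do not fit in the 3' terminus")
  starts <- unique(round(seq(first, last, length.out = n)))
  if (length(starts) < n) stop("windows do not fit in the 3' terminus")
  windows <- Biostrings::DNAStringSet(lapply(starts, function(s)
    subseq(l1Ref, s, s + length - 1L)))
  oligos <- reverseComplement(windows)
  names(oligos) <- paste0("bio", seq_len(n))
  S4Vectors::mcols(oligos)$l1Start <- as.integer(starts)
  oligos
}

## replace occurrences of motif (both strands) until none remain
.scrubMotif <- function(x, motif) {
  rc <- as.character(reverseComplement(Biostrings::DNAString(motif)))
  for (i in 1:100) {
    hits <- c(start(Biostrings::matchPattern(motif, x)),
              start(Biostrings::matchPattern(rc, x)))
    if (length(hits) == 0L) return(x)
    for (s in hits) {
      mid <- s + nchar(motif) %/% 2L
      old <- as.character(subseq(x, mid, mid))
      subseq(x, mid, mid) <- Biostrings::DNAString(
        switch(old, A = "C", T = "G", G = "T", C = "A", "C"))
    }
  }
  stop("could not remove all motif occurrences")
}

#' Simulated target locus with planted endonuclease sites
#'
#' Generates a motif-free background at the requested GC fraction and
#' plants exactly \code{plantedEnSites} copies of the L1 endonuclease
#' nick consensus (default 5'-TTAAAA-3') at recorded positions, guarded
#' by G bases so no extra site arises at a junction.  Optionally plants
#' a pure-A linker (used to build template-switch chimeras) and, if
#' probe oligos are supplied, verifies the locus has no oligo match at
#' \code{maxMismatch} or fewer mismatches, regenerating a bounded number
#' of times if needed.
#'
#' @param length locus length, bp (>= 1000).
#' @param gc background GC fraction.
#' @param plantedEnSites number of motif copies to plant.
#' @param seed integer seed.
#' @param motif endonuclease motif (plus strand).
#' @param oligos optional \link[Biostrings]{DNAStringSet} of probe
#'   oligos the locus must not match.
#' @param maxMismatch mismatch cap for the oligo screen.
#' @param aLinker plant a pure-A linker? (for chimera construction).
#' @param aLinkerLen linker length, nt.
#' @param margin keep planted features at least this far from the ends.
#' @return list with \code{sequence} (DNAString), \code{enSites}
#'   (data.frame, 0-based \code{position} and \code{strand}) and
#'   \code{aLinkerStart} (1-based, or NA).
#' @examples
#' tl <- genTargetLocus(5000, plantedEnSites = 5, seed = 7)
#' nrow(tl$enSites)  # 5
#' @export
genTargetLocus <- function(length, gc = 0.42, plantedEnSites = 5, seed = 1,
                           motif = "TTAAAA", oligos = NULL, maxMismatch = 3,
                           aLinker = FALSE, aLinkerLen = 25, margin = 300) {
  stopifnot(length >= 1000, plantedEnSites >= 0)
  mlen <- nchar(motif)
  for (attempt in 1:10) {
    res <- withSeed(.deriveSeed(seed, paste0("target", attempt)), {
      x <- .scrubMotif(.randomDNA(length, gc), motif)
      linkerStart <- NA_integer_
      if (aLinker) {
        linkerStart <- sample(seq(margin, length - margin - aLinkerLen), 1L)
        subseq(x, linkerStart - 1L, linkerStart + aLinkerLen) <-
          Biostrings::DNAString(paste0("G", strrep("A", aLinkerLen), "G"))
      }
      pos <- integer(0)
      if (plantedEnSites > 0L) {
        lo <- margin
        hi <- length - margin - mlen
        cand <- seq(lo, hi)
        if (aLinker)   # keep clear of the linker
          cand <- cand[abs(cand - linkerStart) > aLinkerLen + 20L]
        ok <- FALSE
        for (draw in 1:50) {
          pos <- sort(sample(cand, plantedEnSites))
          if (plantedEnSites == 1L || min(diff(pos)) > mlen + 20L) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place endonuclease sites")
        for (p in pos)
          subseq(x, p - 1L, p + mlen) <-
            Biostrings::DNAString(paste0("G", motif, "G"))
      }
      list(sequence = x, pos = pos, aLinkerStart = linkerStart)
    })
    found <- countEnSites(res$sequence, motif)
    clean <- nrow(found) == plantedEnSites &&
      all(found$strand == "+") &&
      setequal(found$position, res$pos - 1L)
    if (clean && !is.null(oligos))
      clean <- nrow(scanOligos(res$sequence, oligos, maxMismatch)) == 0L
    if (clean)
      return(list(sequence = res$sequence,
                  enSites = data.frame(position = res$pos - 1L,
                                       strand = rep("+", length(res$pos))),
                  aLinkerStart = res$aLinkerStart))
  }
  stop("could not generate a locus satisfying the constraints")
}

## poly-A tail with optional per-base degradation
.polyATail <- function(n, errorRate) {
  if (n == 0L) return(Biostrings::DNAString(""))
  bases <- rep("A", n)
  if (errorRate > 0) {
    err <- runif(n) < errorRate
    bases[err] <- sample(c("C", "G", "T"), sum(err), replace = TRUE)
  }
  Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Simulated genuine TPRT insertion amplicon
#'
#' Builds an amplicon with the hallmark structure of target-primed
#' reverse transcription: 5' target flank ending in the target site
#' duplication (TSD), a possibly 5'-truncated element in either
#' orientation, a poly-A tail at the element 3' end, and the 3' target
#' flank.  With insertion point p (0-based) and TSD length t, the
#' amplicon is \code{target[0:p+t] + insert + target[p:end]}, i.e. the t
#' bases 5' of the nick are duplicated around the insert.  The insertion
#' point is drawn from the planted endonuclease sites.
#'
#' @param target output of \code{\link{genTargetLocus}} (or a DNAString,
#'   in which case its endonuclease sites are located by scanning).
#' @param l1Ref element sequence from \code{\link{genL1Reference}}.
#' @param config a \linkS4class{SimConfig}; \code{tsdLength},
#'   \code{polyALength}, \code{truncationOffset}, \code{orientation} and
#'   \code{seed} control the structure.
#' @param minFlank minimum flank length retained on both sides, bp.
#' @return list with \code{sequence} (DNAString) and \code{truth}
#'   (a \linkS4class{TruthRecord}).
#' @examples
#' cfg <- simConfig(seed = 3, tsdLength = 15, truncationOffset = 4000)
#' tl <- genTargetLocus(5000, plantedEnSites = 5, seed = 3)
#' amp <- genInsertionAmplicon(tl, genL1Reference(cfg), cfg)
#' @export
genInsertionAmplicon <- function(target, l1Ref, config = simConfig(),
                                 minFlank = 200) {
  stopifnot(is(config, "SimConfig"))
  if (config@truncationOffset >= config@l1Length)
    stop("truncationOffset must be < l1Length")
  l1Ref <- .asDNA(l1Ref, "l1Ref")
  if (is.list(target)) {
    en <- target$enSites
    tseq <- .asDNA(target$sequence, "target")
  } else {
    tseq <- .asDNA(target, "target")
    en <- countEnSites(tseq)
    en <- en[en$strand == "+", , drop = FALSE]
  }
  len <- length(tseq)
  t <- config@tsdLength
  ## nick between TT and AAAA: p = motif position + 2 (0-based)
  cand <- en$position + 2L
  cand <- cand[cand >= minFlank & cand + t <= len - minFlank]
  if (length(cand) == 0L)
    stop("no planted endonuclease site usable as insertion point")
  withSeed(.deriveSeed(config@seed, "amplicon"), {
    p <- cand[sample.int(length(cand), 1L)]
    l1seg <- subseq(l1Ref, config@truncationOffset + 1L, length(l1Ref))
    polyA <- .polyATail(config@polyALength, config@polyAErrorRate)
    element <- Biostrings::xscat(l1seg, polyA)
    insert <- if (config@orientation == "minus")
      reverseComplement(element) else element
    ampl <- Biostrings::xscat(subseq(tseq, 1L, p + t), insert,
                              subseq(tseq, p + 1L, len))
    off <- p + t          # bases before the insert
    nl1 <- length(l1seg); npa <- length(polyA)
    if (config@orientation == "plus") {
      l1Span <- IRanges::IRanges(off + 1L, off + nl1)
      paSpan <- if (npa > 0L)
        IRanges::IRanges(off + nl1 + 1L, off + nl1 + npa)
        else IRanges::IRanges()
    } else {
      paSpan <- if (npa > 0L) IRanges::IRanges(off + 1L, off + npa)
        else IRanges::IRanges()
      l1Span <- IRanges::IRanges(off + npa + 1L, off + npa + nl1)
    }
    truth <- new("TruthRecord", kind = "genuine", insertionPoint = p,
                 tsdSequence = if (t > 0L)
                   as.character(subseq(tseq, p + 1L, p + t)) else "",
                 polyASpan = paSpan, l1Span = l1Span,
                 donorLocusId = NA_character_,
                 junctionPosition = NA_integer_,
                 ampliconLength = length(ampl))
    list(sequence = ampl, truth = truth)
  })
}

#' Donor molecule for chimera construction
#'
#' A locus fragment carrying a pure-A linker immediately 5' of a
#' truncated element with its poly-A tail: the anatomy at which PCR
#' template switching creates target/L1 fusion molecules.
#'
#' @param l1Ref element sequence.
#' @param config a \linkS4class{SimConfig} (truncation, poly-A, seed).
#' @param flank5Len,flank3Len random flank lengths, bp.
#' @param linkerLen pure-A linker length, nt.
#' @return list with \code{sequence}, \code{l1Span}, \code{polyASpan},
#'   \code{aLinkerStart} (all 1-based on the donor).
#' @export
genChimeraDonor <- function(l1Ref, config = simConfig(), flank5Len = 300,
                            flank3Len = 300, linkerLen = 25) {
  stopifnot(is(config, "SimConfig"))
  l1Ref <- .asDNA(l1Ref, "l1Ref")
  withSeed(.deriveSeed(config@seed, "donor"), {
    l1seg <- subseq(l1Ref, config@truncationOffset + 1L, length(l1Ref))
    polyA <- .polyATail(config@polyALength, config@polyAErrorRate)
    f5 <- .randomDNA(flank5Len, config@gcFraction)
    f3 <- .randomDNA(flank3Len, config@gcFraction)
    linker <- Biostrings::DNAString(paste0("G", strrep("A", linkerLen), "G"))
    seqs <- Biostrings::xscat(f5, linker, l1seg, polyA, f3)
    s0 <- flank5Len + linkerLen + 2L     # first base after the linker block
    list(sequence = seqs,
         l1Span = IRanges::IRanges(s0 + 1L, s0 + length(l1seg)),
         polyASpan = if (length(polyA) > 0L)
           IRanges::IRanges(s0 + length(l1seg) + 1L,
                            s0 + length(l1seg) + length(polyA))
           else IRanges::IRanges(),
         aLinkerStart = flank5Len + 2L)
  })
}

## best pure-A window of a given width (first on ties); NULL if the best
## window's A+T content is below minFrac
.findARichTract <- function(x, width = 20L, minFrac = 0.7) {
  x <- .asDNA(x)
  if (length(x) < width) return(NULL)
  v <- Biostrings::letterFrequencyInSlidingView(x, width, "A")[, 1L]
  at <- Biostrings::letterFrequencyInSlidingView(x, width, c("A", "T"))
  atv <- rowSums(at)
  i <- which.max(v)
  if (atv[i] / width < minFrac) return(NULL)
  IRanges::IRanges(i, i + width - 1L)
}

#' Simulated PCR template-switch chimera
#'
#' Fuses a target prefix to a donor suffix at the middle of the A-rich
#' tract each carries, emulating polymerase strand jumping between
#' templates that share an A-rich linker.  The product carries the
#' donor's element 3' end but no target site duplication and no 5'
#' element/target junction.
#'
#' @param target output of \code{\link{genTargetLocus}} with
#'   \code{aLinker = TRUE} (or a DNAString containing an A-rich tract).
#' @param donor output of \code{\link{genChimeraDonor}} (or a DNAString
#'   with an A-rich tract; a donor without an element yields a fusion
#'   molecule that classifies as no insertion).
#' @param seed integer seed (reserved for future stochastic junction
#'   placement; the fusion point is the tract midpoint).
#' @param donorLocusId identifier recorded in the truth record.
#' @return list with \code{sequence} and \code{truth}
#'   (a \linkS4class{TruthRecord} of kind \code{"chimera"}).
#' @export
genChimericAmplicon <- function(target, donor, seed = 1,
                                donorLocusId = "donor") {
  tseq <- if (is.list(target)) .asDNA(target$sequence) else .asDNA(target)
  dseq <- if (is.list(donor)) .asDNA(donor$sequence) else .asDNA(donor)
  ttract <- .findARichTract(tseq)
  dtract <- .findARichTract(dseq)
  if (is.null(ttract) || is.null(dtract))
    stop("no A-rich tract (>= 70% A+T over >= 20 nt) in target or donor")
  tcut <- start(ttract) + width(ttract) %/% 2L   # last prefix base, 1-based
  dcut <- start(dtract) + width(dtract) %/% 2L   # first suffix base, 1-based
  ampl <- Biostrings::xscat(subseq(tseq, 1L, tcut),
                            subseq(dseq, dcut, length(dseq)))
  shift <- tcut + 1L - dcut
  mv <- function(r) if (is.null(r) || length(r) == 0L) IRanges::IRanges()
                    else IRanges::shift(r, shift)
  truth <- new("TruthRecord", kind = "chimera",
               insertionPoint = NA_integer_, tsdSequence = "",
               polyASpan = mv(if (is.list(donor)) donor$polyASpan),
               l1Span = mv(if (is.list(donor)) donor$l1Span),
               donorLocusId = donorLocusId,
               junctionPosition = tcut,   # 0-based first donor base
               ampliconLength = length(ampl))
  list(sequence = ampl, truth = truth)
}

#' Simulated limiting-dilution series
#'
#' Each well receives a Poisson number of amplifiable molecules with
#' mean \code{trueLambda * m}, so it is positive with probability
#' \eqn{1 - e^{-\lambda m}}; well outcomes are independent Bernoulli
#' draws.
#'
#' @param trueLambda amplifiable molecules per pg (>= 0).
#' @param inputsPg vector of per-well DNA inputs, pg (> 0).
#' @param replicates wells per dilution (>= 1).
#' @param seed integer seed.
#' @return a \linkS4class{DilutionSeries}.
#' @examples
#' genDilutionSeries(1/12, c(1, 3, 10, 30, 100), replicates = 8, seed = 1)
#' @export
genDilutionSeries <- function(trueLambda, inputsPg, replicates = 8,
                              seed = 1) {
  stopifnot(trueLambda >= 0, replicates >= 1)
  if (any(inputsPg <= 0)) stop("inputsPg must be positive")
  withSeed(.deriveSeed(seed, "dilution"), {
    p <- -expm1(-trueLambda * inputsPg)
    DilutionSeries(inputsPg,
                   rbinom(length(inputsPg), replicates, p),
                   rep(replicates, length(inputsPg)))
  })
}
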