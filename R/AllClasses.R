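## S4 classes for the insertion-trap screen data model.

#' Parameters of the synthetic-data generator
#'
#' Holds the structural parameters of simulated L1 insertions: element
#' length, target length and base composition, poly-A tail length, target
#' site duplication (TSD) length, 5' truncation offset and orientation.
#' L1 elements are A/T rich, so the element's GC fraction defaults below
#' the genomic background.
#'
#' @slot seed integer seed; a fixed seed gives byte-identical output.
#' @slot l1Length element length, bp (default 6000).
#' @slot targetLength target locus length, bp (default 5000).
#' @slot gcFraction background GC fraction of target loci, in (0,1).
#' @slot l1GcFraction GC fraction of the simulated element, in (0,1).
#' @slot polyALength poly-A tail length, nt.
#' @slot tsdLength target site duplication length, nt (0 = blunt).
#' @slot truncationOffset 5' truncation, bp from the element 5' end;
#'   must satisfy \code{0 <= truncationOffset < l1Length}.
#' @slot orientation \code{"plus"} or \code{"minus"} relative to the
#'   target plus strand.
#' @slot polyAErrorRate per-base substitution rate degrading the poly-A
#'   tail (0 = pure A).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer", l1Length = "integer", targetLength = "integer",
    gcFraction = "numeric", l1GcFraction = "numeric",
    polyALength = "integer", tsdLength = "integer",
    truncationOffset = "integer", orientation = "character",
    polyAErrorRate = "numeric"),
  prototype(
    seed = 1L, l1Length = 6000L, targetLength = 5000L,
    gcFraction = 0.42, l1GcFraction = 0.40,
    polyALength = 20L, tsdLength = 15L,
    truncationOffset = 0L, orientation = "plus",
    polyAErrorRate = 0),
  validity = function(object) {
    msg <- character()
    if (object@l1Length < 2000L)
      msg <- c(msg, "l1Length must be >= 2000 bp")
    if (object@targetLength < 1000L)
      msg <- c(msg, "targetLength must be >= 1000 bp")
    if (object@truncationOffset < 0L ||
        object@truncationOffset >= object@l1Length)
      msg <- c(msg, "truncationOffset must satisfy 0 <= offset < l1Length")
    if (object@tsdLength < 0L) msg <- c(msg, "tsdLength must be >= 0")
    if (object@polyALength < 0L) msg <- c(msg, "polyALength must be >= 0")
    for (s in c("gcFraction", "l1GcFraction")) {
      v <- slot(object, s)
      if (v <= 0 || v >= 1) msg <- c(msg, paste(s, "must be in (0,1)"))
    }
    if (!object@orientation %in% c("plus", "minus"))
      msg <- c(msg, "orientation must be 'plus' or 'minus'")
    if (object@polyAErrorRate < 0 || object@polyAErrorRate > 1)
      msg <- c(msg, "polyAErrorRate must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a \linkS4class{SimConfig}
#'
#' @param seed,l1Length,targetLength,gcFraction,l1GcFraction,polyALength
#'   see the class slots.
#' @param tsdLength,truncationOffset,orientation,polyAErrorRate see the
#'   class slots.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' simConfig(seed = 1, tsdLength = 15, truncationOffset = 4000)
#' @export
simConfig <- function(seed = 1, l1Length = 6000, targetLength = 5000,
                      gcFraction = 0.42, l1GcFraction = 0.40,
                      polyALength = 20, tsdLength = 15,
                      truncationOffset = 0, orientation = "plus",
                      polyAErrorRate = 0) {
  new("SimConfig", seed = as.integer(seed), l1Length = as.integer(l1Length),
      targetLength = as.integer(targetLength), gcFraction = gcFraction,
      l1GcFraction = l1GcFraction, polyALength = as.integer(polyALength),
      tsdLength = as.integer(tsdLength),
      truncationOffset = as.integer(truncationOffset),
      orientation = orientation, polyAErrorRate = polyAErrorRate)
}

#' Ground truth for one simulated amplicon
#'
#' Records how a simulated amplicon was built, for round-trip testing of
#' the classifier.  Intervals are stored as \link[IRanges]{IRanges}
#' (1-based, closed); serialized output is 0-based half-open.
#'
#' @slot kind \code{"genuine"}, \code{"chimera"} or \code{"empty"}.
#' @slot insertionPoint 0-based target coordinate of the nick (genuine
#'   amplicons; \code{NA} otherwise).
#' @slot tsdSequence duplicated target bases (\code{""} if none).
#' @slot polyASpan,l1Span amplicon-coordinate spans (empty if absent).
#' @slot donorLocusId donor locus identifier (chimeras only).
#' @slot junctionPosition 0-based amplicon coordinate of the fusion
#'   junction (chimeras only; \code{NA} otherwise).
#' @slot ampliconLength amplicon length, bp.
#' @exportClass TruthRecord
setClass("TruthRecord",
  representation(
    kind = "character", insertionPoint = "integer", tsdSequence = "character",
    polyASpan = "IRanges", l1Span = "IRanges", donorLocusId = "character",
    junctionPosition = "integer", ampliconLength = "integer"),
  prototype(kind = "empty", insertionPoint = NA_integer_, tsdSequence = "",
            polyASpan = IRanges::IRanges(), l1Span = IRanges::IRanges(),
            donorLocusId = NA_character_, junctionPosition = NA_integer_,
            ampliconLength = 0L),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("genuine", "chimera", "empty"))
      msg <- c(msg, "kind must be genuine, chimera or empty")
    if (object@kind == "genuine" && !is.na(object@donorLocusId))
      msg <- c(msg, "genuine records must not carry a donorLocusId")
    if (object@kind == "chimera" && is.na(object@junctionPosition))
      msg <- c(msg, "chimera records must carry a junctionPosition")
    for (s in c("polyASpan", "l1Span")) {
      r <- slot(object, s)
      if (length(r) && (min(start(r)) < 1L ||
                        max(end(r)) > object@ampliconLength))
        msg <- c(msg, paste(s, "outside amplicon bounds"))
    }
    if (length(msg)) msg else TRUE
  })

#' Limiting-dilution well counts
#'
#' One row per dilution: genomic DNA input per well (pg) and the number
#' of PCR-positive wells out of the total.  Under the single-molecule
#' Poisson model a well is positive with probability
#' \eqn{1 - e^{-\lambda m}} where \eqn{\lambda} is the concentration of
#' amplifiable molecules (molecules/pg) and \eqn{m} the input (pg).
#'
#' @slot inputPg DNA input per well, pg (> 0).
#' @slot wellsPositive positive wells per dilution.
#' @slot wellsTotal total wells per dilution.
#' @exportClass DilutionSeries
setClass("DilutionSeries",
  representation(inputPg = "numeric", wellsPositive = "integer",
                 wellsTotal = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@inputPg)
    if (length(object@wellsPositive) != n || length(object@wellsTotal) != n)
      msg <- c(msg, "slots must have equal length")
    if (any(object@inputPg <= 0)) msg <- c(msg, "inputPg must be > 0")
    if (any(object@wellsPositive < 0L) ||
        any(object@wellsPositive > object@wellsTotal))
      msg <- c(msg, "need 0 <= wellsPositive <= wellsTotal")
    if (any(object@wellsTotal < 1L)) msg <- c(msg, "wellsTotal must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a \linkS4class{DilutionSeries}
#'
#' @param inputPg numeric vector of per-well DNA inputs (pg).
#' @param wellsPositive,wellsTotal integer vectors of well counts.
#' @return a \linkS4class{DilutionSeries}.
#' @examples
#' DilutionSeries(c(1, 10), c(3, 8), c(8, 8))
#' @export
DilutionSeries <- function(inputPg, wellsPositive, wellsTotal) {
  new("DilutionSeries", inputPg = as.numeric(inputPg),
      wellsPositive = as.integer(wellsPositive),
      wellsTotal = as.integer(wellsTotal))
}

#' Poisson estimate of amplifiable-molecule concentration
#'
#' @slot lambdaHat maximum-likelihood concentration, molecules/pg.
#' @slot ciLow,ciHigh profile-likelihood confidence limits, molecules/pg.
#' @slot alpha significance level of the interval (default 0.05).
#' @slot boundaryFlag \code{"none"}, \code{"all_negative"} (MLE 0,
#'   one-sided upper limit) or \code{"all_positive"} (no finite MLE).
#' @exportClass MoleculeEstimate
setClass("MoleculeEstimate",
  representation(lambdaHat = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 alpha = "numeric", boundaryFlag = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@boundaryFlag %in% c("none", "all_negative", "all_positive"))
      msg <- c(msg, "invalid boundaryFlag")
    if (object@boundaryFlag == "none" &&
        !(object@ciLow <= object@lambdaHat &&
          object@lambdaHat <= object@ciHigh))
      msg <- c(msg, "need ciLow <= lambdaHat <= ciHigh")
    if (length(msg)) msg else TRUE
  })

#' Per-cycle PCR gain parameters
#'
#' Empty (insertion-free, ~5 kb) target molecules amplify more
#' efficiently per cycle than filled (~11 kb, L1-containing) molecules.
#'
#' @slot gainEmpty per-cycle multiplicative gain of empty sites.
#' @slot gainFilled per-cycle multiplicative gain of filled sites.
#' @slot cycles number of PCR cycles.
#' @exportClass AmplificationParams
setClass("AmplificationParams",
  representation(gainEmpty = "numeric", gainFilled = "numeric",
                 cycles = "integer"),
  prototype(gainEmpty = 1.8, gainFilled = 1.6, cycles = 20L),
  validity = function(object) {
    msg <- character()
    if (object@gainEmpty < 1 || object@gainEmpty > 2 ||
        object@gainFilled < 1 || object@gainFilled > 2)
      msg <- c(msg, "per-cycle gains must lie in [1,2]")
    if (object@cycles < 0L) msg <- c(msg, "cycles must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname AmplificationParams-class
#' @param gainEmpty,gainFilled,cycles see slots.
#' @return an \linkS4class{AmplificationParams}.
#' @export
amplificationParams <- function(gainEmpty = 1.8, gainFilled = 1.6,
                                cycles = 20) {
  new("AmplificationParams", gainEmpty = gainEmpty, gainFilled = gainFilled,
      cycles = as.integer(cycles))
}

#' Per-round hybridization-enrichment recovery parameters
#'
#' @slot recoveryFilled fraction of L1-containing molecules recovered
#'   per round of enrichment.
#' @slot recoveryEmpty fraction of empty-site molecules carried through
#'   per round.
#' @slot rounds number of enrichment rounds.
#' @exportClass EnrichmentParams
setClass("EnrichmentParams",
  representation(recoveryFilled = "numeric", recoveryEmpty = "numeric",
                 rounds = "integer"),
  prototype(recoveryFilled = 0.02, recoveryEmpty = 4.5e-8, rounds = 1L),
  validity = function(object) {
    msg <- character()
    if (!(object@recoveryEmpty > 0 &&
          object@recoveryEmpty < object@recoveryFilled &&
          object@recoveryFilled <= 1))
      msg <- c(msg, "need 0 < recoveryEmpty < recoveryFilled <= 1")
    if (object@rounds < 0L) msg <- c(msg, "rounds must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname EnrichmentParams-class
#' @param recoveryFilled,recoveryEmpty,rounds see slots.
#' @return an \linkS4class{EnrichmentParams}.
#' @export
enrichmentParams <- function(recoveryFilled = 0.02, recoveryEmpty = 4.5e-8,
                             rounds = 1) {
  new("EnrichmentParams", recoveryFilled = recoveryFilled,
      recoveryEmpty = recoveryEmpty, rounds = as.integer(rounds))
}

#' Filled- and empty-site molecule counts
#'
#' Expected molecule counts (real-valued; rounding is presentation-only)
#' for the L1-containing ("filled") and insertion-free ("empty")
#' compartments, summed over the target panel.
#'
#' @slot filled filled-site molecule count.
#' @slot empty empty-site molecule count over all targets.
#' @slot nTargets number of target loci in the panel.
#' @exportClass MoleculePool
setClass("MoleculePool",
  representation(filled = "numeric", empty = "numeric", nTargets = "integer"),
  validity = function(object) {
    if (object@filled < 0 || object@empty < 0)
      "molecule counts must be >= 0"
    else if (object@nTargets < 1L) "nTargets must be >= 1"
    else TRUE
  })

#' @rdname MoleculePool-class
#' @param filled,empty,nTargets see slots.
#' @return a \linkS4class{MoleculePool}.
#' @export
MoleculePool <- function(filled, empty, nTargets = 10) {
  new("MoleculePool", filled = as.numeric(filled), empty = as.numeric(empty),
      nTargets = as.integer(nTargets))
}

#' Design of the sperm-DNA screen
#'
#' @slot loci data.frame with columns \code{name}, \code{chromosome},
#'   \code{ampliconLengthBp}, \code{xLinked}.
#' @slot dnaMassUg sperm DNA screened, micrograms.
#' @slot pgPerHaploid DNA mass of one haploid (sperm) genome, pg.
#' @slot filledSiteEfficiency single-molecule PCR efficiency for filled
#'   (~12 kb) amplicons, in (0,1].
#' @slot haploidGenomeKb haploid genome size, kb.
#' @slot diploidGenomePg DNA mass of one diploid genome, pg.
#' @exportClass ScreeningDesign
setClass("ScreeningDesign",
  representation(loci = "data.frame", dnaMassUg = "numeric",
                 pgPerHaploid = "numeric", filledSiteEfficiency = "numeric",
                 haploidGenomeKb = "numeric", diploidGenomePg = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("name", "chromosome", "ampliconLengthBp", "xLinked")
    if (!all(need %in% names(object@loci)))
      msg <- c(msg, paste("loci must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(object@loci) == 0L)
      msg <- c(msg, "loci must be non-empty")
    else if (any(object@loci$ampliconLengthBp <= 0))
      msg <- c(msg, "amplicon lengths must be > 0")
    if (any(c(object@dnaMassUg, object@pgPerHaploid, object@haploidGenomeKb,
              object@diploidGenomePg) <= 0))
      msg <- c(msg, "design constants must be positive")
    if (object@filledSiteEfficiency <= 0 || object@filledSiteEfficiency > 1)
      msg <- c(msg, "filledSiteEfficiency must be in (0,1]")
    if (length(msg)) msg else TRUE
  })

#' Upper bound on the insertion frequency
#'
#' @slot eventsUb exact Poisson upper bound on the expected event count.
#' @slot alpha significance level of the bound.
#' @slot kbScreened kilobases of genomic DNA screened.
#' @slot ratePerKb bound on events per kb screened.
#' @slot genomesPerEvent haploid genomes screened per event at the bound.
#' @exportClass FrequencyBound
setClass("FrequencyBound",
  representation(eventsUb = "numeric", alpha = "numeric",
                 kbScreened = "numeric", ratePerKb = "numeric",
                 genomesPerEvent = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@alpha < 1 && object@eventsUb <= 0)
      msg <- c(msg, "eventsUb must be > 0 when alpha < 1")
    if (abs(object@ratePerKb - object@eventsUb / object@kbScreened) >
        1e-9 * max(1, object@ratePerKb))
      msg <- c(msg, "ratePerKb must equal eventsUb / kbScreened")
    if (length(msg)) msg else TRUE
  })

#' Structural annotation of a candidate amplicon
#'
#' Result of \code{\link{classifyAmplicon}}: coordinates (1-based
#' \link[IRanges]{IRanges} on the amplicon, 0-based half-open when
#' serialized), identities, poly-A and TSD calls, the A+T composition at
#' the discordance junction (chimeras), and the verdict with a
#' human-readable evidence trail.
#'
#' @slot id amplicon identifier.
#' @slot verdict one of \code{"genuine"}, \code{"chimera"},
#'   \code{"no_insertion"}, \code{"unresolved"}.
#' @slot flank5,flank3 amplicon-coordinate spans of the target flanks
#'   (empty \code{IRanges} if absent).
#' @slot flank5Target,flank3Target matching target-coordinate spans.
#' @slot flank5Identity,flank3Identity alignment identities (NA if absent).
#' @slot l1Segment amplicon-coordinate span of the L1 segment.
#' @slot l1Orientation \code{"plus"}, \code{"minus"} or \code{NA}.
#' @slot l1TruncationOffset distance (bp) from the element 5' end to the
#'   alignment start on the L1 reference (0-based; NA if no segment).
#' @slot polyA amplicon-coordinate span of the poly-A (or T) tract.
#' @slot polyAPurity A (or T) fraction within the tract.
#' @slot tsd duplicated target sequence (\code{NA} if none found).
#' @slot junctionPosition 0-based amplicon coordinate of the inferred
#'   template-switch junction (chimeras; NA otherwise).
#' @slot junctionATFraction A+T fraction in the window at the junction.
#' @slot evidence character vector of criteria passed/failed.
#' @exportClass InsertionAnnotation
setClass("InsertionAnnotation",
  representation(
    id = "character", verdict = "character",
    flank5 = "IRanges", flank5Target = "IRanges", flank5Identity = "numeric",
    flank3 = "IRanges", flank3Target = "IRanges", flank3Identity = "numeric",
    l1Segment = "IRanges", l1Orientation = "character",
    l1TruncationOffset = "numeric",
    polyA = "IRanges", polyAPurity = "numeric",
    tsd = "character", junctionPosition = "integer",
    junctionATFraction = "numeric", evidence = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@verdict %in%
        c("genuine", "chimera", "no_insertion", "unresolved"))
      msg <- c(msg, "invalid verdict")
    if (object@verdict == "genuine" &&
        (length(object@flank5) == 0L || length(object@flank3) == 0L ||
         length(object@l1Segment) == 0L || length(object@polyA) == 0L))
      msg <- c(msg, "genuine verdict requires flanks, L1 segment and poly-A")
    if (length(msg)) msg else TRUE
  })

#' Target-locus suitability report
#'
#' @slot targetId target identifier.
#' @slot oligoHits data.frame of probe-oligo matches (columns
#'   \code{oligoId}, \code{position} (0-based), \code{strand},
#'   \code{mismatches}).
#' @slot passesOligoScreen TRUE iff no oligo hit at the mismatch cap.
#' @slot enSites data.frame of endonuclease motif sites (columns
#'   \code{position} (0-based), \code{strand}).
#' @slot enDensity motif sites per kb.
#' @slot primerWindows repeat-free intervals (1-based IRanges) long
#'   enough for primer design.
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(targetId = "character", oligoHits = "data.frame",
                 passesOligoScreen = "logical", enSites = "data.frame",
                 enDensity = "numeric", primerWindows = "IRanges"),
  validity = function(object) {
    if (object@passesOligoScreen != (nrow(object@oligoHits) == 0L))
      "passesOligoScreen must mirror an empty oligoHits table"
    else TRUE
  })
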