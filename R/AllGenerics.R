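## Generics, accessors and show methods.

#' @rdname MoleculeEstimate-class
#' @param object a retrotrap S4 object.
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))
#' @rdname MoleculeEstimate-class
#' @export
setGeneric("ciLow", function(object) standardGeneric("ciLow"))
#' @rdname MoleculeEstimate-class
#' @export
setGeneric("ciHigh", function(object) standardGeneric("ciHigh"))
#' @rdname MoleculeEstimate-class
#' @export
setGeneric("boundaryFlag", function(object) standardGeneric("boundaryFlag"))
#' @rdname MoleculeEstimate-class
#' @export
setGeneric("pgPerMolecule", function(object) standardGeneric("pgPerMolecule"))

#' @rdname MoleculeEstimate-class
setMethod("lambdaHat", "MoleculeEstimate", function(object) object@lambdaHat)
#' @rdname MoleculeEstimate-class
setMethod("ciLow", "MoleculeEstimate", function(object) object@ciLow)
#' @rdname MoleculeEstimate-class
setMethod("ciHigh", "MoleculeEstimate", function(object) object@ciHigh)
#' @rdname MoleculeEstimate-class
setMethod("boundaryFlag", "MoleculeEstimate",
          function(object) object@boundaryFlag)
#' @rdname MoleculeEstimate-class
setMethod("pgPerMolecule", "MoleculeEstimate",
          function(object) 1 / object@lambdaHat)

#' @rdname MoleculePool-class
#' @param object a retrotrap S4 object.
#' @export
setGeneric("filled", function(object) standardGeneric("filled"))
#' @rdname MoleculePool-class
#' @export
setGeneric("empty", function(object) standardGeneric("empty"))
#' @rdname MoleculePool-class
#' @export
setGeneric("nTargets", function(object) standardGeneric("nTargets"))

#' @rdname MoleculePool-class
setMethod("filled", "MoleculePool", function(object) object@filled)
#' @rdname MoleculePool-class
setMethod("empty", "MoleculePool", function(object) object@empty)
#' @rdname MoleculePool-class
setMethod("nTargets", "MoleculePool", function(object) object@nTargets)

#' @rdname InsertionAnnotation-class
#' @param object a retrotrap S4 object.
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
#' @rdname InsertionAnnotation-class
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))

#' @rdname InsertionAnnotation-class
setMethod("verdict", "InsertionAnnotation", function(object) object@verdict)
#' @rdname InsertionAnnotation-class
setMethod("evidence", "InsertionAnnotation", function(object) object@evidence)
#' @rdname TruthRecord-class
#' @param object a retrotrap S4 object.
setMethod("verdict", "TruthRecord", function(object) object@kind)

#' @rdname FrequencyBound-class
#' @param object a retrotrap S4 object.
#' @export
setGeneric("eventsUb", function(object) standardGeneric("eventsUb"))
#' @rdname FrequencyBound-class
#' @export
setGeneric("genomesPerEvent",
           function(object) standardGeneric("genomesPerEvent"))
#' @rdname FrequencyBound-class
#' @export
setGeneric("kbScreenedOf", function(object) standardGeneric("kbScreenedOf"))

#' @rdname FrequencyBound-class
setMethod("eventsUb", "FrequencyBound", function(object) object@eventsUb)
#' @rdname FrequencyBound-class
setMethod("genomesPerEvent", "FrequencyBound",
          function(object) object@genomesPerEvent)
#' @rdname FrequencyBound-class
setMethod("kbScreenedOf", "FrequencyBound", function(object) object@kbScreened)

#' Tabular view of a dilution series
#'
#' @param x a \linkS4class{DilutionSeries}.
#' @param ... ignored.
#' @return data.frame with columns \code{input_pg}, \code{wells_positive},
#'   \code{wells_total}.
#' @export
as.data.frame.DilutionSeries <- function(x, ...) {
  data.frame(input_pg = x@inputPg, wells_positive = x@wellsPositive,
             wells_total = x@wellsTotal)
}

setMethod("show", "DilutionSeries", function(object) {
  cat("DilutionSeries with", length(object@inputPg), "dilutions\n")
  print(as.data.frame.DilutionSeries(object))
})

setMethod("show", "MoleculeEstimate", function(object) {
  cat(estimateSummary(object), "\n")
})

setMethod("show", "MoleculePool", function(object) {
  r <- poolRatio(object)
  cat(sprintf(
    "MoleculePool: %.4g filled, %.4g empty (%d targets); ratio 1/%.4g\n",
    object@filled, object@empty, object@nTargets, r$oneInN))
})

setMethod("show", "FrequencyBound", function(object) {
  cat(sprintf(paste0(
    "FrequencyBound: <= %.4g events in %.4g kb (alpha = %.3g)\n",
    "  rate <= %.4g events/kb; < 1 event per %.4g haploid genomes\n"),
    object@eventsUb, object@kbScreened, object@alpha, object@ratePerKb,
    object@genomesPerEvent))
})

setMethod("show", "InsertionAnnotation", function(object) {
  cat(sprintf("InsertionAnnotation '%s': verdict = %s\n",
              object@id, object@verdict))
  fmt <- function(r) if (length(r)) sprintf("[%d,%d)", start(r) - 1L, end(r))
                     else "absent"
  cat("  flank5:", fmt(object@flank5),
      if (length(object@flank5)) sprintf("id %.3f", object@flank5Identity),
      "\n")
  cat("  L1:", fmt(object@l1Segment),
      if (length(object@l1Segment))
        sprintf("%s, 5' truncation %d bp", object@l1Orientation,
                as.integer(object@l1TruncationOffset)), "\n")
  cat("  polyA:", fmt(object@polyA), "\n")
  cat("  flank3:", fmt(object@flank3), "\n")
  if (!is.na(object@junctionPosition))
    cat(sprintf("  junction at %d, A+T fraction %.2f\n",
                object@junctionPosition, object@junctionATFraction))
  for (e in object@evidence) cat("  -", e, "\n")
})

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf(
    "ScreenReport '%s': %s oligo screen; %d EN sites (%.2f/kb); %d primer windows\n",
    object@targetId,
    if (object@passesOligoScreen) "PASSES" else "FAILS",
    nrow(object@enSites), object@enDensity, length(object@primerWindows)))
})

setMethod("show", "TruthRecord", function(object) {
  cat(sprintf("TruthRecord: %s (amplicon %d bp)\n",
              object@kind, object@ampliconLength))
})
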