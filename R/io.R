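## Readers and writers for the pipeline's plain-text formats.
## Sequences travel as FASTA (Biostrings), intervals as BED (0-based
## half-open, rtracklayer), tables as tab-separated text with a
## commented header naming units, and structured results as JSON.

#' Read a limiting-dilution well table
#'
#' Tab-separated, comment lines starting with \code{#}, columns
#' \code{input_pg}, \code{wells_positive}, \code{wells_total}.
#' Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return a \linkS4class{DilutionSeries}.
#' @export
readDilutionSeries <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineNo <- which(keep)
  if (length(lineNo) < 2L)
    stop("dilution table has no data rows: ", path)
  d <- utils::read.delim(text = raw[keep], stringsAsFactors = FALSE)
  need <- c("input_pg", "wells_positive", "wells_total")
  if (!all(need %in% names(d)))
    stop("dilution table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!complete.cases(d[need]) |
                 d$input_pg <= 0 | d$wells_positive < 0 |
                 d$wells_positive > d$wells_total)
  if (length(bad))
    stop("malformed dilution rows at line(s) ",
         paste(lineNo[bad + 1L], collapse = ", "), " of ", path)
  DilutionSeries(d$input_pg, d$wells_positive, d$wells_total)
}

#' Write a limiting-dilution well table
#'
#' @param series a \linkS4class{DilutionSeries}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDilutionSeries <- function(series, path) {
  stopifnot(is(series, "DilutionSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# limiting-dilution well counts",
               "# input_pg: genomic DNA per well (pg); wells out of wells_total PCR-positive"),
             con)
  utils::write.table(as.data.frame.DilutionSeries(series), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## TruthRecord -> plain list (0-based half-open intervals)
.truthToList <- function(truth) {
  list(kind = truth@kind,
       insertion_point = if (is.na(truth@insertionPoint)) NULL
                         else truth@insertionPoint,
       tsd_sequence = truth@tsdSequence,
       polyA_span = .iranges0(truth@polyASpan),
       l1_span = .iranges0(truth@l1Span),
       donor_locus_id = if (is.na(truth@donorLocusId)) NULL
                        else truth@donorLocusId,
       junction_position = if (is.na(truth@junctionPosition)) NULL
                           else truth@junctionPosition,
       amplicon_length = truth@ampliconLength)
}

#' Write truth records as a JSON sidecar
#'
#' @param truths named list of \linkS4class{TruthRecord}s (names are
#'   amplicon ids).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthJSON <- function(truths, path) {
  jsonlite::write_json(lapply(truths, .truthToList), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

## InsertionAnnotation -> plain list (0-based half-open intervals)
.annotationToList <- function(ann) {
  num <- function(x) if (length(x) == 0L || all(is.na(x))) NULL else x
  list(id = ann@id, verdict = ann@verdict,
       flank5 = .iranges0(ann@flank5),
       flank5_target = .iranges0(ann@flank5Target),
       flank5_identity = num(ann@flank5Identity),
       flank3 = .iranges0(ann@flank3),
       flank3_target = .iranges0(ann@flank3Target),
       flank3_identity = num(ann@flank3Identity),
       l1_segment = .iranges0(ann@l1Segment),
       l1_orientation = num(ann@l1Orientation),
       l1_truncation_offset = num(ann@l1TruncationOffset),
       polyA = .iranges0(ann@polyA),
       polyA_purity = num(ann@polyAPurity),
       tsd = num(ann@tsd),
       junction_position = num(ann@junctionPosition),
       junction_at_fraction = num(ann@junctionATFraction),
       evidence = ann@evidence)
}

#' Write amplicon annotations as JSON
#'
#' @param annotations list of \linkS4class{InsertionAnnotation}s.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationJSON <- function(annotations, path) {
  jsonlite::write_json(lapply(annotations, .annotationToList), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

## annotation feature track in amplicon coordinates (one row per feature)
.annotationTrack <- function(ann) {
  feats <- list(flank5 = ann@flank5, l1 = ann@l1Segment,
                polyA = ann@polyA, flank3 = ann@flank3)
  feats <- feats[vapply(feats, length, integer(1)) > 0L]
  if (length(feats) == 0L) return(NULL)
  r <- do.call(c, unname(feats))
  strand <- rep("*", length(r))
  if ("l1" %in% names(feats) && !is.na(ann@l1Orientation))
    strand[match("l1", names(feats))] <-
      if (ann@l1Orientation == "plus") "+" else "-"
  data.frame(seqnames = ann@id, start = start(r), end = end(r),
             strand = strand, name = paste0(ann@id, ":", names(feats)))
}

#' Write annotation feature tracks as BED
#'
#' One BED record per feature (5' flank, L1 segment, poly-A, 3' flank)
#' in amplicon coordinates, 0-based half-open.
#'
#' @param annotations list of \linkS4class{InsertionAnnotation}s.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationBed <- function(annotations, path) {
  trk <- Filter(Negate(is.null),
                unname(lapply(annotations, .annotationTrack)))
  gr <- if (length(trk)) {
    d <- do.call(rbind, trk)
    GenomicRanges::GRanges(seqnames = d$seqnames,
                           ranges = IRanges::IRanges(d$start, d$end),
                           strand = d$strand, name = d$name)
  } else GenomicRanges::GRanges()
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read repeat annotation from BED
#'
#' @param path BED file (0-based half-open).
#' @return \link[IRanges]{IRanges} (1-based) of repeat intervals.
#' @export
readRepeatsBed <- function(path) {
  IRanges::ranges(rtracklayer::import.bed(path))
}

#' Write a molecule estimate as JSON
#'
#' @param estimate a \linkS4class{MoleculeEstimate}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEstimateJSON <- function(estimate, path) {
  stopifnot(is(estimate, "MoleculeEstimate"))
  jsonlite::write_json(list(
    lambda_hat = lambdaHat(estimate), ci_low = ciLow(estimate),
    ci_high = ciHigh(estimate), alpha = estimate@alpha,
    pg_per_molecule = pgPerMolecule(estimate),
    boundary_flag = boundaryFlag(estimate),
    summary = estimateSummary(estimate)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
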