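## Screening-depth inference: from the experimental design to an exact
## zero-event Poisson upper bound on the germline L1 insertion frequency,
## plus interconversions of the literature's incidence formats.

#' Target-locus panel
#'
#' Loads a locus table (tab-separated, columns \code{name},
#' \code{chromosome}, \code{amplicon_length_bp}, \code{x_linked}).  The
#' packaged default is the ten-locus panel of the sperm-DNA screen:
#' eight loci with prior disease-causing L1 insertions plus the HOXD and
#' MHC class II intervals, with BssSI-digest amplicon lengths.
#'
#' @param path path to a locus table; default is the packaged panel.
#' @return data.frame with columns \code{name}, \code{chromosome},
#'   \code{ampliconLengthBp}, \code{xLinked}.
#' @examples
#' loci <- targetLoci()
#' sum(loci$ampliconLengthBp)  # 50819
#' @export
targetLoci <- function(path = system.file("extdata", "target_loci.tsv",
                                          package = "retrotrap")) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "chromosome", "amplicon_length_bp", "x_linked")
  if (!all(need %in% names(d)))
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  data.frame(name = d$name, chromosome = as.character(d$chromosome),
             ampliconLengthBp = as.integer(d$amplicon_length_bp),
             xLinked = as.logical(d$x_linked))
}

#' Construct a \linkS4class{ScreeningDesign}
#'
#' Defaults are the design constants of the screen: 576 ug sperm DNA,
#' 3 pg per haploid genome, 50% single-molecule PCR efficiency for
#' filled (~12 kb) amplicons, a 3x10^6 kb haploid genome and 6 pg per
#' diploid genome.
#'
#' @param loci locus data.frame as returned by \code{\link{targetLoci}}.
#' @param dnaMassUg,pgPerHaploid,filledSiteEfficiency see slots.
#' @param haploidGenomeKb,diploidGenomePg see slots.
#' @return a \linkS4class{ScreeningDesign}.
#' @export
screeningDesign <- function(loci = targetLoci(), dnaMassUg = 576,
                            pgPerHaploid = 3, filledSiteEfficiency = 0.5,
                            haploidGenomeKb = 3e6, diploidGenomePg = 6) {
  new("ScreeningDesign", loci = loci, dnaMassUg = dnaMassUg,
      pgPerHaploid = pgPerHaploid,
      filledSiteEfficiency = filledSiteEfficiency,
      haploidGenomeKb = haploidGenomeKb, diploidGenomePg = diploidGenomePg)
}

#' Total and effective target size of a locus panel
#'
#' X-linked loci are present in only half of sperm, so they contribute
#' half their length to the per-sperm effective target.
#'
#' @param loci locus data.frame (columns \code{ampliconLengthBp},
#'   \code{xLinked}).
#' @return list with \code{totalBp} and \code{effectiveBp}.
#' @examples
#' effectiveTargetSize(targetLoci())  # 50819 total, 37782.5 effective
#' @export
effectiveTargetSize <- function(loci) {
  stopifnot(nrow(loci) > 0)
  len <- loci$ampliconLengthBp
  list(totalBp = sum(len),
       effectiveBp = sum(ifelse(loci$xLinked, len / 2, len)))
}

#' Sperm equivalents in a DNA mass
#'
#' @param massUg DNA mass, micrograms.
#' @param pgPerHaploid pg per haploid genome.
#' @return number of haploid (sperm) genomes, \code{massUg*1e6/pgPerHaploid}.
#' @examples
#' spermCount(576, 3)  # 1.92e8
#' @export
spermCount <- function(massUg, pgPerHaploid) {
  stopifnot(massUg > 0, pgPerHaploid > 0)
  massUg * 1e6 / pgPerHaploid
}

#' Amplifiable molecules of each target
#'
#' Discounts sperm equivalents by the single-molecule PCR efficiency of
#' filled-site amplicons.  The X-chromosome halving is handled in
#' \code{\link{effectiveTargetSize}} (per-sperm target presence), not
#' here.
#'
#' @param sperm haploid genome count.
#' @param efficiency single-molecule PCR efficiency, in (0,1].
#' @return amplifiable molecules per target.
#' @examples
#' amplifiablePerTarget(1.92e8, 0.5)  # 9.6e7
#' @export
amplifiablePerTarget <- function(sperm, efficiency) {
  stopifnot(sperm > 0, efficiency > 0, efficiency <= 1)
  sperm * efficiency
}

#' Kilobases of genomic DNA screened
#'
#' @param effectiveBp effective per-sperm target size, bp.
#' @param molecules amplifiable molecules of each target.
#' @return kb screened, \code{(effectiveBp/1000) * molecules}.
#' @examples
#' kbScreened(38000, 9.6e7)  # 3.648e9
#' @export
kbScreened <- function(effectiveBp, molecules) {
  stopifnot(effectiveBp > 0, molecules > 0)
  (effectiveBp / 1000) * molecules
}

#' Exact one-sided Poisson upper bound
#'
#' Smallest mean \eqn{\lambda} such that
#' \eqn{P(X \le k;\ \lambda) \le \alpha} for an observed count \eqn{k},
#' found by root-finding on the Poisson CDF.  With zero events this is
#' \eqn{-\ln\alpha} (about 3 at \eqn{\alpha = 0.05}).
#'
#' @param observed observed event count (>= 0).
#' @param alpha significance level in (0,1).
#' @return the upper bound on the Poisson mean.
#' @examples
#' poissonUpperBound(0, 0.05)  # 2.9957
#' @export
poissonUpperBound <- function(observed, alpha = 0.05) {
  stopifnot(observed >= 0, alpha > 0, alpha < 1)
  observed <- as.integer(observed)
  if (observed == 0L) return(-log(alpha))
  f <- function(lambda) ppois(observed, lambda) - alpha
  hi <- observed + 20 * sqrt(observed + 1) + 20
  uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Insertion-frequency bound from screening depth
#'
#' @param eventsUb Poisson upper bound on the event count.
#' @param kb kilobases screened.
#' @param haploidGenomeKb haploid genome size, kb.
#' @param alpha significance level carried through for reporting.
#' @return a \linkS4class{FrequencyBound}; \code{genomesPerEvent} is
#'   \code{1 / (ratePerKb * haploidGenomeKb)}.
#' @examples
#' rateBound(poissonUpperBound(0, 0.05), 3.648e9, 3e6)
#' @export
rateBound <- function(eventsUb, kb, haploidGenomeKb = 3e6, alpha = 0.05) {
  stopifnot(eventsUb > 0, kb > 0, haploidGenomeKb > 0)
  rate <- eventsUb / kb
  new("FrequencyBound", eventsUb = eventsUb, alpha = alpha, kbScreened = kb,
      ratePerKb = rate, genomesPerEvent = 1 / (rate * haploidGenomeKb))
}

#' Full screening-depth chain
#'
#' Runs the whole bookkeeping chain from a design: target sizes, sperm
#' and molecule counts, kb screened, the exact Poisson bound for the
#' observed event count, and the headline genomes-per-event figure
#' (raw and floored to the nearest hundred, the convention used when
#' quoting the bound).
#'
#' @param design a \linkS4class{ScreeningDesign}.
#' @param observed observed genuine-insertion count (0 in the screen).
#' @param alpha significance level.
#' @return list with elements \code{totalBp}, \code{effectiveBp},
#'   \code{sperm}, \code{moleculesPerTarget}, \code{kbScreened},
#'   \code{bound} (a \linkS4class{FrequencyBound}),
#'   \code{genomesPerEventFloored} and \code{summary} (one line).
#' @examples
#' screenChain(screeningDesign())$genomesPerEventFloored  # 400
#' @export
screenChain <- function(design = screeningDesign(), observed = 0,
                        alpha = 0.05) {
  stopifnot(is(design, "ScreeningDesign"))
  ts <- effectiveTargetSize(design@loci)
  sperm <- spermCount(design@dnaMassUg, design@pgPerHaploid)
  mol <- amplifiablePerTarget(sperm, design@filledSiteEfficiency)
  kb <- kbScreened(ts$effectiveBp, mol)
  ub <- poissonUpperBound(observed, alpha)
  bound <- rateBound(ub, kb, design@haploidGenomeKb, alpha)
  floored <- floorToNearest(genomesPerEvent(bound), 100)
  list(totalBp = ts$totalBp, effectiveBp = ts$effectiveBp, sperm = sperm,
       moleculesPerTarget = mol, kbScreened = kb, bound = bound,
       genomesPerEventFloored = floored,
       summary = sprintf(
         "<%d insertion%s in %.4g kb (P = %.3g): <1 insertion per %d haploid genomes",
         ceiling(ub), if (ceiling(ub) > 1) "s" else "", kb, alpha,
         as.integer(floored)))
}

#' Incidence to DNA mass per insertion
#'
#' Converts "one de novo insertion per n individuals" into the mass of
#' germline DNA expected to contain one insertion.
#'
#' @param oneInNIndividuals incidence denominator (>= 1).
#' @param diploidPg pg per diploid genome.
#' @return pg of DNA per insertion, \code{n * diploidPg}.
#' @examples
#' incidenceToMass(9, 6)    # 54 pg
#' incidenceToMass(186, 6)  # 1116 pg = 1.12 ng
#' @export
incidenceToMass <- function(oneInNIndividuals, diploidPg = 6) {
  stopifnot(oneInNIndividuals >= 1, diploidPg > 0)
  oneInNIndividuals * diploidPg
}

#' Per-sperm insertion rate into a target
#'
#' Scales a genome-wide incidence ("one insertion per n individuals,
#' anywhere in a diploid genome") down to a target of given size.
#'
#' @param oneInNIndividuals incidence denominator.
#' @param diploidBp diploid genome size, bp (6e9).
#' @param targetBp target size, bp.
#' @return list with \code{ratePerSperm} and \code{spermPerInsertion}.
#' @examples
#' perSpermRate(9, 6e9, 5000)$spermPerInsertion  # ~1.1e7
#' @export
perSpermRate <- function(oneInNIndividuals, diploidBp = 6e9, targetBp) {
  stopifnot(oneInNIndividuals >= 1, diploidBp > 0, targetBp > 0)
  rate <- (1 / oneInNIndividuals) / diploidBp * targetBp
  list(ratePerSperm = rate, spermPerInsertion = 1 / rate)
}

#' Expected insertions per ejaculate
#'
#' @param spermPerInsertion sperm screened per expected insertion.
#' @param ejaculateSperm sperm per ejaculate (~1e8).
#' @return expected insertion count.
#' @examples
#' ejaculateExpectation(1e6, 1e8)  # 100
#' @export
ejaculateExpectation <- function(spermPerInsertion, ejaculateSperm = 1e8) {
  stopifnot(spermPerInsertion > 0, ejaculateSperm > 0)
  ejaculateSperm / spermPerInsertion
}
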