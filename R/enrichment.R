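## Deterministic molecule accounting through multiplex PCR and
## hybridization enrichment.  Expectation model only: per-cycle gains and
## per-round recoveries act multiplicatively; no branching-process
## variance is modelled.

#' Exponential PCR amplification
#'
#' @param n0 starting molecule count (>= 0).
#' @param gain per-cycle multiplicative gain (>= 1; 2 = perfect doubling).
#' @param cycles number of cycles.
#' @return expected molecules, \code{n0 * gain^cycles} (real-valued;
#'   rounding is left to the reporting layer).
#' @examples
#' amplify(1, 1.6, 20)      # 12089.26 -> "12,000" at 2 significant figures
#' amplify(80000, 1.8, 20)  # ~1.02e10 per target
#' @export
amplify <- function(n0, gain, cycles) {
  stopifnot(n0 >= 0, gain >= 1, cycles >= 0)
  n0 * gain^cycles
}

#' Per-cycle gain from endpoint yields
#'
#' Inverse of \code{\link{amplify}}: \code{(nFinal/n0)^(1/cycles)}.
#'
#' @param n0 starting molecules (> 0).
#' @param nFinal final molecules (>= n0).
#' @param cycles number of cycles.
#' @return per-cycle gain.
#' @export
estimateGain <- function(n0, nFinal, cycles) {
  stopifnot(n0 > 0, nFinal >= n0)
  if (cycles == 0) {
    if (nFinal != n0) stop("cycles = 0 but nFinal != n0")
    return(1)
  }
  (nFinal / n0)^(1 / cycles)
}

#' Molecule pool after multiplex PCR
#'
#' Seeds the two compartments from the DNA input and amplifies each with
#' its own per-cycle gain.  Empty-site starts are
#' \code{massUg * 1e6 / genomePg} amplifiable molecules per target
#' (one per genome at 100% single-molecule efficiency), summed over the
#' panel after amplification.
#'
#' @param massUg genomic DNA input, micrograms.
#' @param genomePg DNA mass per genome, pg (6 pg diploid).
#' @param filledStart starting filled-site molecules (e.g. 1 for a
#'   single de novo insertion).
#' @param params an \linkS4class{AmplificationParams}.
#' @param nTargets number of target loci in the multiplex.
#' @return a \linkS4class{MoleculePool}.
#' @examples
#' buildPool(0.5, 6, 1, amplificationParams(), nTargets = 10)
#' @export
buildPool <- function(massUg, genomePg, filledStart = 1,
                      params = amplificationParams(), nTargets = 10) {
  stopifnot(massUg > 0, genomePg > 0, filledStart >= 0,
            is(params, "AmplificationParams"))
  emptyStartPerTarget <- massUg * 1e6 / genomePg
  MoleculePool(
    filled = amplify(filledStart, params@gainFilled, params@cycles),
    empty = nTargets * amplify(emptyStartPerTarget, params@gainEmpty,
                               params@cycles),
    nTargets = nTargets)
}

#' Apply rounds of hybridization enrichment
#'
#' Each round keeps a fraction \code{recoveryFilled} of L1-containing
#' molecules and \code{recoveryEmpty} of empty-site molecules, so
#' \code{rounds} rounds scale the compartments by those fractions to the
#' power \code{rounds}.  Enrichment never increases counts.
#'
#' @param pool a \linkS4class{MoleculePool}.
#' @param params an \linkS4class{EnrichmentParams}.
#' @return the enriched \linkS4class{MoleculePool}.
#' @examples
#' enrich(MoleculePool(12000, 1e11), enrichmentParams(rounds = 1))
#' @export
enrich <- function(pool, params = enrichmentParams()) {
  stopifnot(is(pool, "MoleculePool"), is(params, "EnrichmentParams"))
  MoleculePool(
    filled = pool@filled * params@recoveryFilled^params@rounds,
    empty = pool@empty * params@recoveryEmpty^params@rounds,
    nTargets = pool@nTargets)
}

#' Filled-to-empty molecule ratio
#'
#' @param pool a \linkS4class{MoleculePool} with \code{empty > 0}.
#' @return list with \code{ratio} (filled/empty) and \code{oneInN}
#'   (empty/filled), i.e. the "1 in N" form.
#' @examples
#' poolRatio(MoleculePool(12000, 1e11))$oneInN  # 8.33e6
#' @export
poolRatio <- function(pool) {
  stopifnot(is(pool, "MoleculePool"))
  if (pool@empty <= 0) stop("empty compartment is zero; ratio undefined")
  list(ratio = pool@filled / pool@empty, oneInN = pool@empty / pool@filled)
}

#' Probability an aliquot contains a filled molecule
#'
#' Poisson sampling of an aliquot seeding the screening PCR: an aliquot
#' holding a fraction \code{aliquotFraction} of a pool with
#' \code{filled} molecules contains at least one with probability
#' \eqn{1 - e^{-\mathrm{filled} \cdot \mathrm{fraction}}}.
#'
#' @param filled filled-site molecule count in the pool.
#' @param aliquotFraction fraction of the pool sampled, in (0,1].
#' @return detection probability.
#' @export
detectionProbability <- function(filled, aliquotFraction) {
  stopifnot(filled >= 0, aliquotFraction > 0, aliquotFraction <= 1)
  -expm1(-filled * aliquotFraction)
}

#' Stage-by-stage enrichment ledger
#'
#' Runs the accounting chain (seed, PCR, each enrichment round) and
#' returns one row per stage; the shape used for tab-separated output.
#'
#' @inheritParams buildPool
#' @param eparams an \linkS4class{EnrichmentParams}; its \code{rounds}
#'   slot sets how many enrichment rows are produced.
#' @return data.frame with columns \code{stage}, \code{filled},
#'   \code{empty}, \code{ratio_one_in_n}.
#' @export
enrichmentLedger <- function(massUg = 0.5, genomePg = 6, filledStart = 1,
                             params = amplificationParams(),
                             nTargets = 10,
                             eparams = enrichmentParams()) {
  seed <- MoleculePool(filledStart, nTargets * massUg * 1e6 / genomePg,
                       nTargets)
  pcr <- buildPool(massUg, genomePg, filledStart, params, nTargets)
  stages <- list(seed = seed, multiplex_pcr = pcr)
  pool <- pcr
  one <- enrichmentParams(eparams@recoveryFilled, eparams@recoveryEmpty, 1)
  for (r in seq_len(eparams@rounds)) {
    pool <- enrich(pool, one)
    stages[[paste0("enrichment_round_", r)]] <- pool
  }
  data.frame(
    stage = names(stages),
    filled = vapply(stages, filled, numeric(1)),
    empty = vapply(stages, empty, numeric(1)),
    ratio_one_in_n = vapply(stages, function(p) poolRatio(p)$oneInN,
                            numeric(1)),
    row.names = NULL)
}
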