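## Limiting-dilution Poisson estimation of amplifiable molecules.
##
## Model: a well seeded with m pg of genomic DNA is PCR-positive iff it
## received >= 1 amplifiable molecule; molecule counts are Poisson with
## mean lambda * m, so P(positive) = 1 - exp(-lambda * m).

#' Closed-form single-dilution Poisson estimate
#'
#' At a single dilution the zero class gives the maximum-likelihood
#' concentration directly:
#' \eqn{\hat\lambda = -\ln(\mathrm{neg}/\mathrm{total}) / m}.
#'
#' @param wellsNegative number of PCR-negative wells (must be >= 1; with
#'   no negatives the estimate is unbounded).
#' @param wellsTotal total wells.
#' @param inputPg DNA input per well, pg.
#' @return molecules per pg.
#' @examples
#' lambdaFromSingleDilution(5, 8, 1)  # -log(5/8) = 0.4700
#' @export
lambdaFromSingleDilution <- function(wellsNegative, wellsTotal, inputPg) {
  stopifnot(wellsTotal >= 1, inputPg > 0)
  if (wellsNegative <= 0)
    stop("no negative wells: the single-dilution estimate is unbounded")
  if (wellsNegative > wellsTotal)
    stop("wellsNegative exceeds wellsTotal")
  -log(wellsNegative / wellsTotal) / inputPg
}

## binomial log-likelihood of a series at concentration lambda
## (constants dropped)
.dilutionLogLik <- function(lambda, m, k, n) {
  p <- -expm1(-lambda * m)            # 1 - exp(-lambda m), accurately
  ll <- numeric(length(m))
  pos <- k > 0L
  ll[pos] <- k[pos] * log(p[pos])
  ll - lambda * m * (n - k)
}

#' Estimate molecule concentration from a dilution series
#'
#' Maximizes the product-binomial likelihood
#' \deqn{L(\lambda) = \prod_i {n_i \choose k_i}
#'   (1 - e^{-\lambda m_i})^{k_i} (e^{-\lambda m_i})^{n_i - k_i}}
#' over all dilutions jointly: the score function is strictly
#' decreasing in \eqn{\lambda}, so the MLE is found by bounded
#' root-finding over [1e-6, 1e3] molecules/pg.  The confidence
#' interval is the profile-likelihood set at the chi-squared(1 df)
#' cutoff, found by root-finding on the deviance.  On a single-dilution
#' series the MLE equals the closed form of
#' \code{\link{lambdaFromSingleDilution}}.
#'
#' All-negative series return an MLE of 0 with a one-sided upper limit;
#' series positive at every well of every dilution have no finite MLE
#' and are flagged \code{"all_positive"} (lambdaHat = Inf).
#'
#' @param series a \linkS4class{DilutionSeries}.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return a \linkS4class{MoleculeEstimate}.
#' @examples
#' s <- DilutionSeries(1, wellsPositive = 3, wellsTotal = 8)
#' lambdaHat(estimateMolecules(s))   # -log(5/8)
#' @export
estimateMolecules <- function(series, alpha = 0.05) {
  stopifnot(is(series, "DilutionSeries"), alpha > 0, alpha < 1)
  m <- series@inputPg; k <- series@wellsPositive; n <- series@wellsTotal
  lo <- 1e-6; hi <- 1e3
  cut <- qchisq(1 - alpha, df = 1)
  ll <- function(lambda) sum(.dilutionLogLik(lambda, m, k, n))

  if (all(k == n)) {
    ## every well positive: likelihood increases without bound
    dev <- function(lambda) -2 * ll(lambda) - cut     # llmax -> 0
    lower <- uniroot(dev, c(lo, hi), tol = 1e-12)$root
    return(new("MoleculeEstimate", lambdaHat = Inf, ciLow = lower,
               ciHigh = Inf, alpha = alpha, boundaryFlag = "all_positive"))
  }
  if (all(k == 0L)) {
    ## MLE 0; deviance 2*lambda*sum(n m) crosses the cutoff once
    upper <- cut / (2 * sum(n * m))
    return(new("MoleculeEstimate", lambdaHat = 0, ciLow = 0,
               ciHigh = upper, alpha = alpha, boundaryFlag = "all_negative"))
  }

  ## the score (d logLik / d lambda) is strictly decreasing, so the MLE
  ## is its unique root; root-finding reaches full numerical precision
  score <- function(lambda) {
    em <- exp(-lambda * m)
    sum(k * m * em / (1 - em) - m * (n - k))
  }
  lhat <- if (score(lo) <= 0) lo
    else if (score(hi) >= 0) hi
    else uniroot(score, c(lo, hi), tol = 1e-14)$root
  llmax <- ll(lhat)
  dev <- function(lambda) 2 * (llmax - ll(lambda)) - cut
  ciLow <- if (dev(lo) > 0)
    uniroot(dev, c(lo, lhat), tol = 1e-12)$root else 0
  ciHigh <- uniroot(dev, c(lhat, hi), tol = 1e-12)$root
  new("MoleculeEstimate", lambdaHat = lhat, ciLow = ciLow, ciHigh = ciHigh,
      alpha = alpha, boundaryFlag = "none")
}

#' Single-molecule PCR efficiency
#'
#' Ratio of the observed amplifiable-molecule concentration to the
#' concentration expected if every genomic copy were amplifiable
#' (\code{copies} per genome of \code{genomePg} pg).  Values above 1
#' indicate an inconsistent calibration and are reported with a warning.
#'
#' @param estimate a \linkS4class{MoleculeEstimate}.
#' @param genomePg DNA mass per genome carrying \code{copies}, pg
#'   (e.g. 6 pg per diploid genome).
#' @param copiesPerGenome amplifiable copies of the locus per genome
#'   (1 for a heterozygous insertion, 2 for homozygous/empty autosomal).
#' @return efficiency as a fraction.
#' @examples
#' est <- new("MoleculeEstimate", lambdaHat = 1/12, ciLow = 1/19,
#'            ciHigh = 1/7, alpha = 0.05, boundaryFlag = "none")
#' pcrEfficiency(est, genomePg = 6, copiesPerGenome = 1)  # 0.5
#' @export
pcrEfficiency <- function(estimate, genomePg, copiesPerGenome = 1) {
  stopifnot(is(estimate, "MoleculeEstimate"), genomePg > 0,
            copiesPerGenome >= 1)
  eff <- lambdaHat(estimate) / (copiesPerGenome / genomePg)
  if (is.finite(eff) && eff > 1)
    warning(sprintf("efficiency %.3g exceeds 1; check genome mass and copy number",
                    eff))
  eff
}

#' One-line summary of a molecule estimate
#'
#' Formats the estimate the way screen calibrations are usually quoted:
#' "1 molecule per X pg (95% CI a-b pg)".
#'
#' @param estimate a \linkS4class{MoleculeEstimate}.
#' @return character scalar.
#' @export
estimateSummary <- function(estimate) {
  stopifnot(is(estimate, "MoleculeEstimate"))
  pct <- 100 * (1 - estimate@alpha)
  switch(estimate@boundaryFlag,
    all_negative = sprintf(
      "no positive wells: lambda = 0 (one-sided %g%% upper limit %.3g molecules/pg)",
      pct, estimate@ciHigh),
    all_positive = sprintf(
      "all wells positive: no finite estimate (%g%% lower limit %.3g molecules/pg)",
      pct, estimate@ciLow),
    sprintf("1 molecule per %.3g pg (%g%% CI %.3g-%.3g pg)",
            1 / estimate@lambdaHat, pct,
            1 / estimate@ciHigh, 1 / estimate@ciLow))
}
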