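# Screening depth and the zero-event Poisson frequency bound.

test_that("the packaged locus panel gives the published target sizes", {
  loci <- targetLoci()
  expect_identical(nrow(loci), 10L)
  ts <- effectiveTargetSize(loci)
  expect_identical(ts$totalBp, 50819L)
  expect_equal(ts$effectiveBp, 37782.5)
  expect_equal(round(ts$totalBp / 1000), 51)
  expect_equal(round(ts$effectiveBp / 1000), 38)
  # all-autosomal panels lose nothing
  auto <- loci; auto$xLinked <- FALSE
  expect_equal(effectiveTargetSize(auto)$effectiveBp, sum(loci$ampliconLengthBp))
})

test_that("sperm and amplifiable-molecule counts follow from mass and efficiency", {
  expect_equal(spermCount(576, 3), 1.92e8)
  expect_equal(toSigFigs(spermCount(576, 3), 2), 1.9e8)
  expect_equal(spermCount(3e-6, 3), 1)
  # diploid convention used when seeding the PCR pool
  expect_equal(spermCount(0.5, 6), 0.5e6 / 6)
  expect_equal(toSigFigs(spermCount(0.5, 6), 1), 8e4)
  expect_equal(amplifiablePerTarget(1.92e8, 0.5), 9.6e7)
  expect_equal(amplifiablePerTarget(100, 1), 100)
  expect_equal(amplifiablePerTarget(100, 0.5), 50)
})

test_that("kb screened multiplies effective target size by molecule count", {
  expect_equal(kbScreened(38000, 9.6e7), 3.648e9)
  expect_equal(kbScreened(1000, 1), 1)
  expect_equal(kbScreened(37782.5, 9.6e7), 3.627e9, tolerance = 1e-4)
})

test_that("the exact Poisson upper bound matches closed forms and a CDF-scan oracle", {
  expect_equal(poissonUpperBound(0, 0.05), -log(0.05), tolerance = 1e-9)
  expect_equal(round(poissonUpperBound(0, 0.05), 3), 2.996)
  expect_equal(poissonUpperBound(0, exp(-1)), 1, tolerance = 1e-9)
  expect_equal(poissonUpperBound(2, 0.05), poissonUBOracle(2, 0.05),
               tolerance = 2e-4)
  expect_equal(round(poissonUpperBound(2, 0.05), 3), 6.296)
  # gamma-quantile identity as an independent cross-check
  for (k in 0:4)
    expect_equal(poissonUpperBound(k, 0.05), qgamma(0.95, k + 1),
                 tolerance = 1e-8)
  # monotone in the observed count, decreasing in alpha
  ub <- vapply(0:5, poissonUpperBound, numeric(1), alpha = 0.05)
  expect_true(all(diff(ub) > 0))
  expect_gt(poissonUpperBound(0, 0.01), poissonUpperBound(0, 0.10))
})

test_that("rate bounds convert kb screened into genomes per event", {
  b <- rateBound(poissonUpperBound(0, 0.05), 3.648e9, 3e6)
  expect_equal(genomesPerEvent(b), 406, tolerance = 0.01)
  expect_equal(floorToNearest(genomesPerEvent(b), 100), 400)
  bPaperKb <- rateBound(poissonUpperBound(0, 0.05), 3.7e9, 3e6)
  expect_equal(floorToNearest(genomesPerEvent(bPaperKb), 100), 400)
  expect_equal(genomesPerEvent(rateBound(1, 3e6, 3e6)), 1)
  # linear scaling in kb
  b2 <- rateBound(poissonUpperBound(0, 0.05), 2 * 3.648e9, 3e6)
  expect_equal(b2@ratePerKb, b@ratePerKb / 2)
  expect_equal(genomesPerEvent(b2), 2 * genomesPerEvent(b))
})

test_that("the full design chain floors to 400 haploid genomes per event", {
  ch <- screenChain(screeningDesign())
  expect_equal(ch$sperm, 1.92e8)
  expect_equal(ch$moleculesPerTarget, 9.6e7)
  expect_equal(ch$kbScreened, 3.627e9, tolerance = 1e-4)
  expect_identical(ch$genomesPerEventFloored, 400)
  expect_match(ch$summary, "400 haploid genomes")
  # the rounded-constant chain lands on the same headline figure
  rounded <- kbScreened(38000, 9.6e7)
  expect_identical(
    floorToNearest(genomesPerEvent(rateBound(poissonUpperBound(0, 0.05),
                                             rounded, 3e6)), 100), 400)
})

test_that("incidence conversions match the literature formats", {
  expect_equal(incidenceToMass(9, 6), 54)
  expect_equal(incidenceToMass(186, 6), 1116)
  expect_equal(toSigFigs(incidenceToMass(186, 6) / 1000, 3), 1.12)  # ng
  expect_equal(incidenceToMass(1, 6), 6)
})

test_that("per-sperm rates scale genome-wide incidence down to the target", {
  one <- perSpermRate(9, 6e9, 5000)
  expect_equal(one$spermPerInsertion, 1.08e7)
  expect_equal(round(log10(one$spermPerInsertion)), 7)
  panel <- perSpermRate(9, 6e9, 37782.5)
  expect_equal(panel$spermPerInsertion, 1.43e6, tolerance = 1e-3)
  expect_equal(round(log10(panel$spermPerInsertion)), 6)
  # a target of n genome-equivalents concentrates the incidence to one
  # event per sperm
  expect_equal(perSpermRate(9, 6e9, 9 * 6e9)$ratePerSperm, 1)
})

test_that("ejaculate expectations follow from the per-sperm rate", {
  expect_equal(ejaculateExpectation(1e6, 1e8), 100)
  expect_equal(ejaculateExpectation(1e8, 1e8), 1)
  expect_equal(ejaculateExpectation(perSpermRate(9, 6e9, 37782.5)$spermPerInsertion,
                                    1e8), 70, tolerance = 0.01)
})

test_that("reporting helpers round the way headline numbers are quoted", {
  expect_equal(toSigFigs(12089.3, 2), 12000)
  expect_equal(floorToNearest(406, 100), 400)
  expect_equal(toSigFigs(1.116, 3), 1.12)
})
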