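# Limiting-dilution Poisson estimation.

test_that("single-dilution closed form matches the zero-class formula and a grid oracle", {
  expect_equal(lambdaFromSingleDilution(8, 8, 1), 0)
  expect_equal(lambdaFromSingleDilution(5, 8, 1), -log(5 / 8))
  expect_equal(round(lambdaFromSingleDilution(5, 8, 1), 4), 0.4700)
  # scaling by input mass
  expect_equal(lambdaFromSingleDilution(5, 8, 2),
               lambdaFromSingleDilution(5, 8, 1) / 2)
  # cross-check against grid maximization of the Bernoulli likelihood
  grid <- gridMLEOracle(m = 1, k = 3, n = 8)
  expect_equal(lambdaFromSingleDilution(5, 8, 1), grid, tolerance = 1e-3)
  expect_error(lambdaFromSingleDilution(0, 8, 1), "unbounded")
  expect_error(lambdaFromSingleDilution(9, 8, 1), "exceeds")
})

test_that("multi-dilution MLE equals the closed form on single-row series", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:16, 1)
    k <- sample(seq_len(n - 1), 1)    # at least one negative, one positive
    m <- runif(1, 0.5, 50)
    est <- estimateMolecules(DilutionSeries(m, k, n))
    expect_equal(lambdaHat(est), lambdaFromSingleDilution(n - k, n, m),
                 tolerance = 1e-9)
    expect_lt(ciLow(est), lambdaHat(est))
    expect_gt(ciHigh(est), lambdaHat(est))
  }
})

test_that("multi-dilution MLE agrees with grid maximization", {
  s <- DilutionSeries(c(1, 3, 10, 30), c(1, 2, 5, 7), c(8, 8, 8, 8))
  grid <- gridMLEOracle(s@inputPg, s@wellsPositive, s@wellsTotal)
  expect_equal(lambdaHat(estimateMolecules(s)), grid, tolerance = 1e-3)
})

test_that("boundary series are flagged instead of silently estimated", {
  allNeg <- estimateMolecules(DilutionSeries(c(1, 10), c(0, 0), c(8, 8)))
  expect_identical(boundaryFlag(allNeg), "all_negative")
  expect_identical(lambdaHat(allNeg), 0)
  expect_identical(ciLow(allNeg), 0)
  expect_gt(ciHigh(allNeg), 0)
  # deviance at the upper limit equals the chi-squared cutoff
  expect_equal(2 * sum(8 * c(1, 10)) * ciHigh(allNeg),
               qchisq(0.95, 1), tolerance = 1e-9)

  allPos <- estimateMolecules(DilutionSeries(c(1, 10), c(8, 8), c(8, 8)))
  expect_identical(boundaryFlag(allPos), "all_positive")
  expect_identical(lambdaHat(allPos), Inf)
  expect_gt(ciLow(allPos), 0)
})

test_that("lambda estimates respond monotonically to extra positive wells", {
  base <- DilutionSeries(c(1, 5), c(2, 4), c(8, 8))
  lam <- vapply(0:8, function(k) {
    s <- DilutionSeries(c(1, 5, 10), c(2, 4, k), c(8, 8, 8))
    est <- estimateMolecules(s)
    if (is.finite(lambdaHat(est))) lambdaHat(est) else Inf
  }, numeric(1))
  expect_true(all(diff(lam) >= -1e-8))
})

test_that("profile CI covers the generating concentration at near-nominal rate", {
  # 1 molecule per 12 pg, the calibration regime of filled-site controls
  lam <- 1 / 12
  inputs <- c(1, 3, 10, 30, 100)
  hits <- 0L
  nSim <- 200L
  for (i in seq_len(nSim)) {
    est <- estimateMolecules(genDilutionSeries(lam, inputs, 8, seed = i))
    if (boundaryFlag(est) == "none" &&
        ciLow(est) <= lam && lam <= ciHigh(est)) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.93)
})

test_that("PCR efficiency converts molecule yield into per-copy terms", {
  mkEst <- function(pgPerMol) new("MoleculeEstimate", lambdaHat = 1 / pgPerMol,
                                  ciLow = 0, ciHigh = 1, alpha = 0.05,
                                  boundaryFlag = "none")
  expect_equal(pcrEfficiency(mkEst(12), genomePg = 6, copiesPerGenome = 1), 0.5)
  expect_equal(pcrEfficiency(mkEst(6), genomePg = 6, copiesPerGenome = 1), 1.0)
  expect_equal(pcrEfficiency(mkEst(6), genomePg = 6, copiesPerGenome = 2), 0.5)
  expect_warning(pcrEfficiency(mkEst(3), genomePg = 6, copiesPerGenome = 1),
                 "exceeds 1")
})

test_that("dilution tables survive a write/read round trip and reject bad rows", {
  s <- genDilutionSeries(0.2, c(1, 5, 25), 8, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDilutionSeries(s, path)
  s2 <- readDilutionSeries(path)
  expect_equal(as.data.frame(s), as.data.frame(s2))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("input_pg\twells_positive\twells_total",
               "1\t3\t8", "2\t9\t8"), bad)
  expect_error(readDilutionSeries(bad), "line\\(s\\) 3")

  headerOnly <- withr::local_tempfile(fileext = ".tsv")
  writeLines("input_pg\twells_positive\twells_total", headerOnly)
  expect_error(readDilutionSeries(headerOnly), "no data rows")
})

test_that("estimate summaries quote the pg-per-molecule convention", {
  est <- estimateMolecules(DilutionSeries(1, 3, 8))
  expect_match(estimateSummary(est), "^1 molecule per .* pg \\(95% CI")
})
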