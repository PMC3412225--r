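# Synthetic-data generators: determinism, planted structure, ground truth.

cfgSmall <- function(seed = 1, ...) {
  simConfig(seed = seed, l1Length = 2000, targetLength = 1200, ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- cfgSmall(seed = 9)
  expect_identical(as.character(genL1Reference(cfg)),
                   as.character(genL1Reference(cfg)))
  t1 <- genTargetLocus(1200, plantedEnSites = 4, seed = 9)
  t2 <- genTargetLocus(1200, plantedEnSites = 4, seed = 9)
  expect_identical(as.character(t1$sequence), as.character(t2$sequence))
  expect_identical(t1$enSites, t2$enSites)
  d1 <- genDilutionSeries(0.1, c(1, 10), 8, seed = 9)
  d2 <- genDilutionSeries(0.1, c(1, 10), 8, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("different seeds give substantially different elements", {
  for (s in 1:10) {
    a <- strsplit(as.character(genL1Reference(cfgSmall(seed = s))), "")[[1]]
    b <- strsplit(as.character(genL1Reference(cfgSmall(seed = s + 100))), "")[[1]]
    expect_gt(mean(a != b), 0.10)
  }
})

test_that("element length below the minimum is rejected", {
  expect_error(simConfig(seed = 1, l1Length = 1000), "l1Length")
})

test_that("probe oligos are reverse complements of 3'-terminal windows", {
  l1 <- genL1Reference(cfgSmall(seed = 2))
  oligos <- genBioOligos(l1, n = 4, length = 30)
  expect_length(oligos, 4L)
  hits <- scanOligos(l1, oligos, maxMismatch = 0)
  expect_identical(nrow(hits), 4L)
  expect_true(all(hits$strand == "-"))       # complementary to the element
  expect_true(all(hits$position >= length(l1) - 1500))
  # a single full-window oligo is the complement of the whole terminus
  full <- genBioOligos(l1, n = 1, length = 1500)
  expect_identical(as.character(full[[1]]),
                   as.character(Biostrings::reverseComplement(
                     subseq(l1, length(l1) - 1499, length(l1)))))
  # no cross-hybridization with the element 5' half, even at 3 mismatches
  # (element long enough that the 5' half is clear of the probe windows)
  l1long <- genL1Reference(simConfig(seed = 2, l1Length = 3500))
  oligosLong <- genBioOligos(l1long, 4, 30)
  half <- subseq(l1long, 1, length(l1long) %/% 2)
  expect_identical(nrow(scanOligos(half, oligosLong, maxMismatch = 3)), 0L)
  expect_error(genBioOligos(l1, n = 4, length = 1501), "1500")
  expect_error(genBioOligos(l1, n = 2000, length = 1500), "fit")
})

test_that("target loci carry exactly the planted endonuclease sites", {
  tl <- genTargetLocus(5000, plantedEnSites = 5, seed = 7)
  en <- countEnSites(tl$sequence)
  expect_gte(nrow(en), 5L)
  expect_identical(nrow(en), 5L)
  expect_setequal(en$position, tl$enSites$position)
  clean <- genTargetLocus(2000, plantedEnSites = 0, seed = 7)
  expect_identical(nrow(countEnSites(clean$sequence)), 0L)
  # no probe-oligo match at <= 3 mismatches when oligos are supplied
  l1 <- genL1Reference(cfgSmall(seed = 7))
  oligos <- genBioOligos(l1, 4, 30)
  tl2 <- genTargetLocus(1500, plantedEnSites = 3, seed = 7, oligos = oligos)
  expect_identical(nrow(scanOligos(tl2$sequence, oligos, 3)), 0L)
  expect_error(genTargetLocus(800, plantedEnSites = 1, seed = 1), ">= 1000")
})

test_that("genuine amplicons assemble flanks, TSD, element and tail correctly", {
  cfg <- cfgSmall(seed = 13, tsdLength = 15, polyALength = 20,
                  truncationOffset = 0)
  l1 <- genL1Reference(cfg)
  tl <- genTargetLocus(1200, plantedEnSites = 3, seed = 13)
  amp <- genInsertionAmplicon(tl, l1, cfg)
  # full-length insert: exact length bookkeeping
  expect_identical(length(amp$sequence),
                   1200L + 2000L + 20L + 15L)
  tr <- amp$truth
  expect_identical(tr@kind, "genuine")
  expect_identical(width(tr@l1Span), 2000L)
  expect_identical(width(tr@polyASpan), 20L)
  expect_identical(nchar(tr@tsdSequence), 15L)
  # the element span on the amplicon is the (truncated) element verbatim
  expect_identical(as.character(subseq(amp$sequence, start(tr@l1Span),
                                       end(tr@l1Span))),
                   as.character(l1))
  expect_error(genInsertionAmplicon(tl, l1,
                                    cfgSmall(seed = 1, truncationOffset = 2000)),
               "truncationOffset")
})

test_that("minus-orientation inserts carry the element on the reverse strand", {
  cfg <- cfgSmall(seed = 14, truncationOffset = 600, orientation = "minus")
  l1 <- genL1Reference(cfg)
  tl <- genTargetLocus(1200, plantedEnSites = 3, seed = 14)
  amp <- genInsertionAmplicon(tl, l1, cfg)
  seg <- locateL1(amp$sequence, l1)
  expect_identical(seg$orientation, "minus")
  # alignment-based truncation recovers the planted offset closely
  expect_lt(abs(seg$truncationOffset - 600), 25)
})

test_that("chimeras fuse at A-rich tracts and carry the donor element", {
  cfg <- cfgSmall(seed = 15, truncationOffset = 900)
  l1 <- genL1Reference(cfg)
  tl <- genTargetLocus(1200, plantedEnSites = 3, seed = 15, aLinker = TRUE)
  donor <- genChimeraDonor(l1, cfg)
  chi <- genChimericAmplicon(tl, donor, donorLocusId = "d1")
  tr <- chi$truth
  expect_identical(tr@kind, "chimera")
  expect_identical(tr@donorLocusId, "d1")
  expect_false(is.na(tr@junctionPosition))
  # composition at the recorded junction is A/T rich
  expect_gte(junctionComposition(chi$sequence, tr@junctionPosition + 1L, 20),
             0.7)
  # no A-rich tract -> reported failure
  gcOnly <- Biostrings::DNAString(
    retrotrap:::withSeed(1, randomDNAString(1200, gc = 0.95)))
  expect_error(genChimericAmplicon(gcOnly, gcOnly), "A-rich")
})

test_that("truth records enforce their structural invariants", {
  expect_error(new("TruthRecord", kind = "chimera",
                   junctionPosition = NA_integer_, ampliconLength = 100L),
               "junctionPosition")
  expect_error(new("TruthRecord", kind = "genuine",
                   donorLocusId = "x", ampliconLength = 100L),
               "donorLocusId")
  expect_error(new("TruthRecord", kind = "genuine",
                   l1Span = IRanges::IRanges(90, 150),
                   ampliconLength = 100L),
               "bounds")
})

test_that("dilution outcomes follow the Poisson positive-well probability", {
  expect_true(all(genDilutionSeries(0, c(1, 10, 100), 8, 1)@wellsPositive == 0L))
  sat <- genDilutionSeries(0.5, 100, 8, 2)      # lambda*m = 50
  expect_true(all(sat@wellsPositive == 8L))
  expect_error(genDilutionSeries(0.1, c(-1, 2), 8, 1), "positive")
  # empirical positive fractions within 3 binomial SE of 1 - exp(-lambda m)
  lam <- 0.15; inputs <- c(1, 5, 20); reps <- 40L
  tally <- matrix(0, length(inputs), 2)
  for (s in 1:25) {
    d <- genDilutionSeries(lam, inputs, reps, seed = 500 + s)
    tally[, 1] <- tally[, 1] + d@wellsPositive
    tally[, 2] <- tally[, 2] + d@wellsTotal
  }
  p <- -expm1(-lam * inputs)
  se <- sqrt(p * (1 - p) / tally[, 2])
  expect_true(all(abs(tally[, 1] / tally[, 2] - p) <= 3 * se))
})
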