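# Structural classification of candidate amplicons.

smallCase <- function(seed, ...) {
  cfg <- simConfig(seed = seed, l1Length = 2000, targetLength = 1200, ...)
  l1 <- genL1Reference(cfg)
  tl <- genTargetLocus(1200, plantedEnSites = 3, seed = seed)
  list(cfg = cfg, l1 = l1, tl = tl)
}

test_that("local alignment scores agree with an exhaustive DP oracle", {
  th <- classifierThresholds()
  set.seed(71)
  for (i in 1:6) {
    shared <- randomDNAString(60)
    p <- paste0(randomDNAString(80), shared, randomDNAString(60))
    # mutate the shared block a little so gaps and mismatches appear
    sv <- strsplit(shared, "")[[1]]
    sv[sample(60, 4)] <- sample(c("A", "C", "G", "T"), 4, TRUE)
    s <- paste0(randomDNAString(50), paste(sv, collapse = ""),
                randomDNAString(90))
    got <- retrotrap:::.swLocal(Biostrings::DNAString(p),
                                Biostrings::DNAString(s), th)
    expect_equal(got$score, swOracle(p, s))
  }
})

test_that("flank alignment recovers target flanks around an insertion", {
  cs <- smallCase(41, tsdLength = 12, truncationOffset = 800)
  # exact copy of the target: one full-length flank, no internal insertion
  fl <- alignFlanks(cs$tl$sequence, cs$tl$sequence)
  expect_true(fl$fullMatch)
  expect_null(fl$flank3)
  # genuine amplicon: two flanks whose target coordinates abut at the
  # insertion point (within the TSD plus alignment slack)
  amp <- genInsertionAmplicon(cs$tl, cs$l1, cs$cfg)
  fl2 <- alignFlanks(amp$sequence, cs$tl$sequence)
  expect_false(is.null(fl2$flank5))
  expect_false(is.null(fl2$flank3))
  p <- amp$truth@insertionPoint
  expect_lt(abs(end(fl2$flank5$target) - (p + 12)), 12 + 6)
  expect_lt(abs(start(fl2$flank3$target) - (p + 1)), 12 + 6)
  # chimera: the 5' end maps to the target, the 3' end does not
  tlc <- genTargetLocus(1200, plantedEnSites = 3, seed = 42, aLinker = TRUE)
  chi <- genChimericAmplicon(tlc, genChimeraDonor(cs$l1, cs$cfg))
  fl3 <- alignFlanks(chi$sequence, tlc$sequence)
  expect_false(is.null(fl3$flank5))
  expect_null(fl3$flank3)
  expect_error(alignFlanks("ACGT", "ACGT"), ">= 500")
})

test_that("element location reports orientation and 5' truncation", {
  cs <- smallCase(43, truncationOffset = 0)
  amp <- genInsertionAmplicon(cs$tl, cs$l1, cs$cfg)
  seg <- locateL1(amp$sequence, cs$l1)
  expect_identical(seg$orientation, "plus")
  expect_identical(seg$truncationOffset, 0L)
  cs2 <- smallCase(44, truncationOffset = 700)
  amp2 <- genInsertionAmplicon(cs2$tl, cs2$l1, cs2$cfg)
  expect_lt(abs(locateL1(amp2$sequence, cs2$l1)$truncationOffset - 700), 25)
  # an amplicon without element sequence yields nothing
  expect_null(locateL1(cs$tl$sequence, cs$l1))
})

test_that("poly-A tracts are found at the element junction, strand-aware", {
  set.seed(45)
  left <- randomDNAString(300, gc = 0.6)
  right <- randomDNAString(300, gc = 0.6)
  clean <- Biostrings::DNAString(paste0(left, strrep("A", 20), right))
  hit <- findPolyA(clean, anchor = 301)
  expect_gte(width(hit$range), 18)
  expect_gte(hit$purity, 0.9)
  # no tract, no call
  expect_null(findPolyA(Biostrings::DNAString(paste0(left, right)), 301))
  # minus-strand insertions leave a T tract searched leftward
  cleanT <- Biostrings::DNAString(paste0(left, strrep("T", 20), right))
  hitT <- findPolyA(cleanT, anchor = 320, orientation = "minus")
  expect_gte(width(hitT$range), 18)
  expect_gte(hitT$purity, 0.9)
})

test_that("TSDs are the overlap of the flank projections on the target", {
  # direct construction: breaks overlapping by 15 bases
  set.seed(46)
  tgt <- Biostrings::DNAString(randomDNAString(2000))
  got <- findTSD(tgt, leftBreak = 1015, rightBreak = 1001)
  expect_identical(got$length, 15L)
  expect_identical(got$sequence, as.character(subseq(tgt, 1001, 1015)))
  # blunt insertion: no overlap, no TSD
  expect_null(findTSD(tgt, leftBreak = 1000, rightBreak = 1001))
  # round trip through the classifier: planted TSD recovered
  cs <- smallCase(47, tsdLength = 15, truncationOffset = 500)
  amp <- genInsertionAmplicon(cs$tl, cs$l1, cs$cfg)
  ann <- classifyAmplicon(amp$sequence, cs$tl$sequence, cs$l1)
  expect_false(is.na(ann@tsd))
  expect_lt(abs(nchar(ann@tsd) - 15), 5)
})

test_that("junction composition measures local A/T content", {
  expect_equal(junctionComposition(strrep("A", 50), 25, 20), 1.0)
  set.seed(48)
  x <- randomDNAString(4000, gc = 0.5)
  at <- vapply(seq(100, 3900, by = 100), function(p)
    junctionComposition(x, p, 20), numeric(1))
  se <- sqrt(0.5 * 0.5 / 20)
  expect_true(all(abs(at - 0.5) <= 3.5 * se))
  linked <- paste0(randomDNAString(200), strrep("A", 25), randomDNAString(200))
  expect_gte(junctionComposition(linked, 213, 20), 0.95)
})

test_that("verdicts follow the genuine / chimera / empty rules", {
  cs <- smallCase(49, tsdLength = 10, truncationOffset = 400,
                  polyALength = 20)
  amp <- genInsertionAmplicon(cs$tl, cs$l1, cs$cfg)
  ann <- classifyAmplicon(amp$sequence, cs$tl$sequence, cs$l1, id = "g")
  expect_identical(verdict(ann), "genuine")
  expect_true(any(grepl("TPRT", evidence(ann))))
  # chimera: single flank, A/T-rich junction
  tlc <- genTargetLocus(1200, plantedEnSites = 3, seed = 50, aLinker = TRUE)
  chi <- genChimericAmplicon(tlc, genChimeraDonor(cs$l1, cs$cfg))
  annc <- classifyAmplicon(chi$sequence, tlc$sequence, cs$l1, id = "c")
  expect_identical(verdict(annc), "chimera")
  expect_gte(annc@junctionATFraction, 0.7)
  # fusion with a donor lacking any element: no insertion to report
  noL1donor <- Biostrings::DNAString(paste0(
    retrotrap:::withSeed(51, randomDNAString(400, gc = 0.42)),
    "G", strrep("A", 25), "G",
    retrotrap:::withSeed(52, randomDNAString(500, gc = 0.42))))
  chi2 <- genChimericAmplicon(tlc, noL1donor)
  expect_identical(verdict(classifyAmplicon(chi2$sequence, tlc$sequence,
                                            cs$l1)), "no_insertion")
  # empty-site amplicon
  expect_identical(verdict(classifyAmplicon(cs$tl$sequence, cs$tl$sequence,
                                            cs$l1)), "no_insertion")
  # unreadable sequences raise errors, not verdicts
  expect_error(classifyAmplicon("ACGTX", cs$tl$sequence, cs$l1), "characters")
  expect_error(classifyAmplicon(strrep("A", 50), cs$tl$sequence, cs$l1),
               ">= 100")
})

test_that("annotated intervals are coherent on the amplicon", {
  cs <- smallCase(53, tsdLength = 8, truncationOffset = 900)
  amp <- genInsertionAmplicon(cs$tl, cs$l1, cs$cfg)
  ann <- classifyAmplicon(amp$sequence, cs$tl$sequence, cs$l1)
  len <- length(amp$sequence)
  for (r in list(ann@flank5, ann@l1Segment, ann@polyA, ann@flank3)) {
    expect_gte(start(r), 1L)
    expect_lte(end(r), len)
  }
  expect_lt(end(ann@flank5), start(ann@l1Segment) + 30)
  expect_lt(end(ann@l1Segment), start(ann@flank3) + 30)
  # re-extraction check: the flank5 span really is target sequence
  f5 <- subseq(amp$sequence, start(ann@flank5), end(ann@flank5))
  t5 <- subseq(cs$tl$sequence, start(ann@flank5Target),
               end(ann@flank5Target))
  eq <- mean(strsplit(as.character(f5), "")[[1]][
    seq_len(min(length(f5), length(t5)))] ==
    strsplit(as.character(t5), "")[[1]][seq_len(min(length(f5), length(t5)))])
  expect_gte(eq, 0.9)
})
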