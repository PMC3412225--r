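# Target-locus suitability screening.

test_that("oligo scanning finds planted variants up to the mismatch cap", {
  set.seed(61)
  bg <- randomDNAString(3000)
  oligo <- randomDNAString(30)
  mutate <- function(x, k) {
    v <- strsplit(x, "")[[1]]
    at <- sample(length(v), k)
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  oligos <- Biostrings::DNAStringSet(c(probe = oligo))
  # verbatim plant
  tgt <- Biostrings::DNAString(paste0(substr(bg, 1, 1000), oligo,
                                      substr(bg, 1001, 3000)))
  hits <- scanOligos(tgt, oligos, 3)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 1000L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$strand, "+")
  # three substitutions reported, four not
  tgt3 <- Biostrings::DNAString(paste0(substr(bg, 1, 1000), mutate(oligo, 3),
                                       substr(bg, 1001, 3000)))
  expect_identical(scanOligos(tgt3, oligos, 3)$mismatches, 3L)
  tgt4 <- Biostrings::DNAString(paste0(substr(bg, 1, 1000), mutate(oligo, 4),
                                       substr(bg, 1001, 3000)))
  expect_identical(nrow(scanOligos(tgt4, oligos, 3)), 0L)
  # reverse-complement plant is a minus-strand hit
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(oligo)))
  tgtRC <- Biostrings::DNAString(paste0(substr(bg, 1, 500), rc,
                                        substr(bg, 501, 3000)))
  hitsRC <- scanOligos(tgtRC, oligos, 0)
  expect_identical(hitsRC$strand, "-")
  expect_identical(hitsRC$position, 500L)
})

test_that("oligo scanning agrees exactly with the naive Hamming oracle", {
  for (s in 1:4) {
    set.seed(600 + s)
    tgt <- Biostrings::DNAString(randomDNAString(2500, gc = 0.42))
    # oligos partly related to the target so near-misses occur
    o1 <- as.character(subseq(tgt, 201, 228))
    v <- strsplit(o1, "")[[1]]
    v[c(4, 11)] <- c("A", "C")
    oligos <- Biostrings::DNAStringSet(c(a = paste(v, collapse = ""),
                                         b = randomDNAString(24)))
    got <- scanOligos(tgt, oligos, 3)
    want <- hammingScanOracle(tgt, oligos, 3)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("endonuclease site census counts both strands", {
  one <- countEnSites("GGTTAAAAGG")
  expect_identical(one$position, 2L)
  expect_identical(one$strand, "+")
  rev <- countEnSites("GGTTTTAAGG")
  expect_identical(rev$position, 2L)
  expect_identical(rev$strand, "-")
  expect_identical(nrow(countEnSites("GGGGCCCCGGGGCCCC")), 0L)
  expect_equal(attr(countEnSites("GGTTAAAAGG"), "density"), 1 / (10 / 1000))
  # counting a sequence equals counting its reverse complement with
  # strands swapped
  set.seed(62)
  x <- Biostrings::DNAString(randomDNAString(5000, gc = 0.35))
  fwd <- countEnSites(x)
  rc <- countEnSites(Biostrings::reverseComplement(x))
  expect_identical(nrow(fwd), nrow(rc))
  expect_identical(sum(fwd$strand == "+"), sum(rc$strand == "-"))
})

test_that("primer windows are the repeat-free complement above the length cut", {
  # no repeats: the whole target is one window
  w <- primerWindows(1000, NULL, minWindow = 50)
  expect_identical(start(w), 1L)
  expect_identical(end(w), 1000L)
  # repeats covering everything
  expect_length(primerWindows(1000, IRanges::IRanges(1, 1000), 50), 0L)
  # overlapping repeats are merged: [100,200) u [150,300) on 1000 bp
  w2 <- primerWindows(1000, data.frame(start = c(100, 150),
                                       end = c(200, 300)), minWindow = 50)
  expect_identical(start(w2), c(1L, 301L))
  expect_identical(end(w2), c(100L, 1000L))
  # property: disjoint, sorted, equal to the occupancy-vector oracle
  set.seed(63)
  for (i in 1:10) {
    L <- sample(500:10000, 1)
    nrep <- sample(0:8, 1)
    s0 <- sort(sample(0:(L - 10), nrep))
    e0 <- pmin(L, s0 + sample(5:400, nrep, TRUE))
    got <- primerWindows(L, data.frame(start = s0, end = e0), minWindow = 40)
    want <- windowsOracle(L, s0, e0, 40)
    expect_identical(as.data.frame(got), as.data.frame(want))
    if (length(got) > 1) expect_true(all(diff(start(got)) > 0))
  }
})

test_that("screen reports tie the three criteria together", {
  set.seed(64)
  l1 <- genL1Reference(simConfig(seed = 64, l1Length = 2000))
  oligos <- genBioOligos(l1, 4, 30)
  tl <- genTargetLocus(1500, plantedEnSites = 4, seed = 64, oligos = oligos)
  rep1 <- screenTarget(tl$sequence, oligos, targetId = "clean")
  expect_true(rep1@passesOligoScreen)
  expect_identical(nrow(rep1@enSites), 4L)
  expect_gt(rep1@enDensity, 0)
  expect_identical(start(rep1@primerWindows), 1L)
  # planting an oligo variant fails the screen
  v <- strsplit(as.character(oligos[[1]]), "")[[1]]
  v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
  dirty <- Biostrings::DNAString(paste0(
    as.character(subseq(tl$sequence, 1, 700)), paste(v, collapse = ""),
    as.character(subseq(tl$sequence, 701, 1500))))
  rep2 <- screenTarget(dirty, oligos, targetId = "dirty")
  expect_false(rep2@passesOligoScreen)
  expect_lte(min(rep2@oligoHits$mismatches), 1L)
})
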