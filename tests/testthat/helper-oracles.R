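# Independent brute-force oracles used to cross-check the implementation.

# exhaustive affine-gap local alignment (gap of length L costs open + ext*L)
swOracle <- function(p, s, match = 1, mismatch = -1, open = 2, ext = 1) {
  p <- strsplit(p, "")[[1]]
  s <- strsplit(s, "")[[1]]
  n <- length(p); m <- length(s)
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- if (p[i - 1] == s[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0) + sc
    Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
    if (M[i, j] > best) best <- M[i, j]
  }
  best
}

# naive all-windows Hamming scan of oligos against both strands
hammingScanOracle <- function(target, oligos, maxMismatch) {
  tch <- strsplit(as.character(target), "")[[1]]
  revcomp <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  rows <- list()
  ids <- names(oligos)
  for (i in seq_along(oligos)) {
    for (str in c("+", "-")) {
      o <- as.character(oligos[[i]])
      if (str == "-") o <- revcomp(o)
      och <- strsplit(o, "")[[1]]
      w <- length(och)
      for (s in seq_len(length(tch) - w + 1L)) {
        mm <- sum(tch[s:(s + w - 1L)] != och)
        if (mm <= maxMismatch)
          rows[[length(rows) + 1L]] <- data.frame(
            oligoId = ids[i], position = s - 1L, strand = str,
            mismatches = mm)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(oligoId = character(), position = integer(),
                         strand = character(), mismatches = integer())
  out[order(out$position, out$oligoId, out$strand), , drop = FALSE]
}

# interval complement via a logical occupancy vector
windowsOracle <- function(targetLength, starts0, ends0, minWindow) {
  occ <- logical(targetLength)
  for (i in seq_along(starts0)) {
    if (ends0[i] > starts0[i]) occ[(starts0[i] + 1L):ends0[i]] <- TRUE
  }
  r <- rle(occ)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  keep <- !r$values & r$lengths >= minWindow
  IRanges::IRanges(s[keep], e[keep])
}

# zero/k-event Poisson upper bound by brute-force scan of the CDF
poissonUBOracle <- function(k, alpha, step = 1e-4) {
  lam <- step
  while (ppois(k, lam) > alpha) lam <- lam + step
  lam
}

# grid maximization of the dilution-series Bernoulli likelihood
gridMLEOracle <- function(m, k, n, grid = exp(seq(log(1e-4), log(50), length.out = 20001))) {
  ll <- vapply(grid, function(l)
    sum(k * log(1 - exp(-l * m)) - l * m * (n - k)), numeric(1))
  grid[which.max(ll)]
}

randomDNAString <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, prob = p), collapse = "")
}
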