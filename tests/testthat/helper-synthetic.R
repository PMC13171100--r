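# fixture builders shared across test files (everything is generated in
# code; no binary fixtures)

# digital disk mask of radius r (logical matrix)
diskMask <- function(r, pad = 3L) {
  sz <- 2L * r + 2L * pad
  cc <- (sz + 1) / 2
  outer(seq_len(sz), seq_len(sz),
        function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

# 1 x len horizontal rod mask
rodMask <- function(len, pad = 3L) {
  m <- matrix(FALSE, 2L * pad + 1L, len + 2L * pad)
  m[pad + 1L, pad + seq_len(len)] <- TRUE
  m
}

# movie with one rectangular-pulse event on a given footprint:
# dff = amp inside footprint during frames f0:f1, 0 elsewhere
pulseMovie <- function(footprint, f0, f1, nT, amp = 1) {
  d <- dim(footprint)
  arr <- array(0, c(d, nT))
  for (t in f0:f1) arr[, , t] <- footprint * amp
  arr
}

# anti-aliased horizontal tube stack: width w0 * mod[t] px, centred
tubeMovie <- function(fov, w0, mods, lo = 10, hi = 200) {
  nT <- length(mods)
  arr <- array(lo, c(fov, fov, nT))
  rowOff <- abs(seq_len(fov) - fov %/% 2)
  for (t in seq_len(nT)) {
    edge <- pmin(pmax(mods[t] * w0 / 2 - rowOff + 0.5, 0), 1)
    arr[, , t] <- lo + (hi - lo) * matrix(edge, fov, fov)
  }
  arr
}

# brute-force O(n^2) interval-overlap oracle for synchronization tests
bruteSyncOracle <- function(tb, tol = 0) {
  out <- list()
  n <- nrow(tb)
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    if (j > n) break
    if (tb$cell_id[i] == tb$cell_id[j]) next
    if (tb$t0_s[i] - tol / 2 <= tb$t1_s[j] + tol / 2 &&
        tb$t0_s[j] - tol / 2 <= tb$t1_s[i] + tol / 2) {
      a <- i; b <- j
      if (tb$cell_id[b] < tb$cell_id[a]) { a <- j; b <- i }
      out[[length(out) + 1L]] <- data.frame(
        cellA = tb$cell_id[a], cellB = tb$cell_id[b],
        latency = tb$t0_s[a] - tb$t0_s[b])
    }
  }
  if (!length(out)) return(data.frame(cellA = character(),
                                      cellB = character(),
                                      latency = numeric()))
  do.call(rbind, out)
}

# random small event table for the oracle comparison
randomEventTable <- function(nEvents, nCells, tMax = 100, seed = 1) {
  set.seed(seed)
  t0 <- runif(nEvents, 0, tMax)
  data.frame(cell_id = sample(LETTERS[seq_len(nCells)], nEvents, TRUE),
             t0_s = t0, t1_s = t0 + runif(nEvents, 1, 15),
             stringsAsFactors = FALSE)
}
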