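# Waveform conditioning, frequency-domain features, elbow-selected k-means
# clustering of cell activity, and cluster-vs-niche association testing.

#' Condition a dF/F0 trace (detrend + Savitzky-Golay smooth) by SNR search
#'
#' The trace is first detrended by subtracting a wide-window Savitzky-Golay
#' baseline (order 2, window `detrendWindow` samples), then smoothed with
#' the (polynomial order, window length) pair that maximizes
#' `SNR = var(filtered) / var(residual)` over an exhaustive grid. Constant
#' traces have no defined SNR and are flagged; near-zero residual variance
#' (e.g. a noiseless sinusoid) caps the SNR at `snrCap` and flags the cell.
#'
#' @param trace numeric dF/F0 series
#' @param orders polynomial orders searched (default 2:5)
#' @param windows odd window lengths searched (default 5-101)
#' @param detrendWindow detrending window, samples (clipped to trace length)
#' @param snrCap cap applied when the residual variance underflows
#' @return list with `trace` (conditioned), `polyorder`, `window`, `snr`,
#'   `flagged`
#' @export
conditionTrace <- function(trace, orders = 2:5, windows = seq(5L, 101L, 2L),
                           detrendWindow = 301L, snrCap = 1e6) {
  n <- length(trace)
  if (n < min(windows))
    stop("trace shorter than the smallest smoothing window")
  if (var(trace) == 0)
    return(list(trace = trace - mean(trace), polyorder = NA_integer_,
                window = NA_integer_, snr = NA_real_, flagged = TRUE))
  dw <- oddify(min(detrendWindow, n))
  det <- trace - signal::sgolayfilt(trace, p = 2, n = dw)
  best <- list(snr = -Inf)
  flagged <- FALSE
  for (w in windows[windows <= n]) {
    # p >= w - 1 reproduces the input exactly (zero residual); excluded so
    # the SNR comparison stays meaningful
    for (p in orders[orders < w - 1L]) {
      sm <- signal::sgolayfilt(det, p = p, n = w)
      rv <- var(det - sm)
      snr <- if (rv < .Machine$double.eps) snrCap else var(sm) / rv
      if (snr > best$snr)
        best <- list(snr = snr, p = p, w = w, sm = sm)
    }
  }
  if (best$snr >= snrCap) flagged <- TRUE
  list(trace = best$sm, polyorder = best$p, window = best$w,
       snr = min(best$snr, snrCap), flagged = flagged)
}

#' Dominant frequency of a detrended trace
#'
#' Argmax of the raw periodogram excluding the zero-frequency bin, reported
#' at the bin-centre frequency `k * rateHz / N`.
#'
#' @param trace detrended numeric series
#' @param rateHz sampling rate, Hz
#' @return frequency in Hz, or `NA` (with a warning) for an all-zero trace
#' @export
dominantFrequency <- function(trace, rateHz = 1.03) {
  n <- length(trace)
  if (all(trace == 0)) {
    warning("all-zero trace: dominant frequency undefined")
    return(NA_real_)
  }
  pw <- Mod(fft(trace))^2
  half <- 2:(floor(n / 2) + 1L)
  k <- half[which.max(pw[half])] - 1L
  k * rateHz / n
}

#' Count peaks by prominence
#'
#' Local maxima whose topographic prominence is at least
#' `prominenceFrac * (max - min)` of the trace.
#'
#' @param trace numeric series
#' @param prominenceFrac prominence threshold as a fraction of the signal
#'   amplitude range (default 0.10)
#' @return integer peak count
#' @export
countPeaks <- function(trace, prominenceFrac = 0.10) {
  n <- length(trace)
  if (n < 3L) return(0L)
  isMax <- which(diff(sign(diff(trace))) < 0) + 1L
  if (!length(isMax)) return(0L)
  rng <- diff(range(trace))
  if (rng == 0) return(0L)
  thr <- prominenceFrac * rng
  count <- 0L
  for (p in isMax) {
    h <- trace[p]
    # walk left/right to the first sample exceeding the peak; the key saddle
    # on each side is the minimum over that stretch
    lSeg <- trace[seq_len(p - 1L)]
    hiL <- which(lSeg > h)
    keyL <- if (length(hiL)) min(lSeg[(max(hiL) + 1L):(p - 1L)]) else
      min(c(lSeg, h))
    rSeg <- trace[(p + 1L):n]
    hiR <- which(rSeg > h)
    keyR <- if (length(hiR)) min(rSeg[seq_len(min(hiR) - 1L)]) else
      min(c(rSeg, h))
    prom <- h - max(keyL, keyR)
    if (prom >= thr) count <- count + 1L
  }
  count
}

#' Spectral features for a set of cells
#'
#' Runs [conditionTrace()], [dominantFrequency()] and [countPeaks()] per cell
#' and assembles the clustering feature table.
#'
#' @param dff a [DffTraces-class] or cells x time matrix
#' @param rateHz sampling rate (taken from `dff` when it is a `DffTraces`)
#' @param ... passed to [conditionTrace()]
#' @return data.frame: cell_id, polyorder, window, snr, domfreq_hz, n_peaks,
#'   flagged
#' @export
spectralFeatures <- function(dff, rateHz = 1.03, ...) {
  m <- if (is(dff, "DffTraces")) { rateHz <- dff@rateHz; dff@traces } else dff
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(nrow(m)))
  out <- lapply(seq_len(nrow(m)), function(i) {
    ct <- conditionTrace(m[i, ], ...)
    df <- if (ct$flagged && is.na(ct$snr)) NA_real_ else
      dominantFrequency(ct$trace, rateHz)
    data.frame(cell_id = ids[i], polyorder = ct$polyorder,
               window = ct$window, snr = ct$snr, domfreq_hz = df,
               n_peaks = countPeaks(ct$trace), flagged = ct$flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# within-cluster sum of squares over a k range (nstart restarts, seeded)
.wssCurve <- function(X, kRange, nstart, seed) {
  withSeed(seed, vapply(kRange, function(k) {
    if (k == 1L) return(sum(scale(X, scale = FALSE)^2))
    if (k > nrow(unique(X))) return(NA_real_)
    kmeans(X, centers = k, nstart = nstart, iter.max = 100L)$tot.withinss
  }, numeric(1L)))
}

#' Choose k by the elbow rule
#'
#' Computes the within-cluster sum of squares (WSS) over `kRange` (best of
#' `nstart` k-means restarts under a fixed seed) and returns the largest k
#' whose second difference of the WSS curve is a genuine elbow: strength
#' `d2(k)/WSS(k-1) >= 0.5` (about 1 at a true cluster count, about 0.2 on
#' the smooth single-blob decay). A flat curve with no such k -- a single
#' homogeneous blob -- returns k = 1, as do degenerate identical rows.
#'
#' @param X feature matrix (cells x features)
#' @param kRange candidate cluster counts (default 1:6)
#' @param nstart k-means restarts per k
#' @param seed RNG seed for the restarts
#' @return the chosen k
#' @export
chooseKElbow <- function(X, kRange = 1:6, nstart = 20L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 cells")
  if (nrow(unique(X)) == 1L) return(1L)
  kRange <- sort(kRange[kRange <= nrow(X)])
  wss <- .wssCurve(X, kRange, nstart, seed)
  if (length(kRange) < 3L) return(kRange[1L])
  inner <- 2:(length(kRange) - 1L)
  d2 <- wss[inner - 1L] - 2 * wss[inner] + wss[inner + 1L]
  # elbow strength: second difference relative to the WSS it bends from;
  # ~1 at a true cluster count, ~0.2 on the smooth single-blob decay
  strength <- d2 / wss[inner - 1L]
  cand <- inner[is.finite(strength) & strength >= 0.5]
  if (!length(cand)) return(1L)
  kRange[max(cand)]
}

#' k-means clustering of cell spectral features
#'
#' Features are z-scored per column, then clustered with k-means using
#' `nstart` restarts under a fixed seed (best inertia kept). Cluster labels
#' are renumbered by decreasing cluster size so the majority population is
#' always cluster 1 of the relabelled output ... the published convention
#' numbers the small multi-frequency population first, so an `orderBy`
#' argument selects `"size"` (default, ascending cluster index = descending
#' size) or `"none"`.
#'
#' @param X feature matrix (cells x features); rownames are cell ids
#' @param k number of clusters
#' @param seed RNG seed
#' @param nstart restarts (default 20)
#' @param orderBy label ordering convention
#' @return list with `labels` (named integer vector), `k`, `centers`
#'   (z-scored space), and the `scaling` record
#' @export
clusterCells <- function(X, k, seed = 1L, nstart = 20L,
                         orderBy = c("size", "none")) {
  orderBy <- match.arg(orderBy)
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k cannot exceed the number of cells")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(nrow(X)))
  mu <- colMeans(X); sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  if (k == 1L)
    return(list(labels = setNames(rep(1L, nrow(X)), ids), k = 1L,
                centers = matrix(colMeans(Z), 1L),
                scaling = list(mean = mu, sd = sdv)))
  km <- withSeed(seed, kmeans(Z, centers = k, nstart = nstart,
                              iter.max = 100L))
  labels <- km$cluster
  if (orderBy == "size") {
    ord <- order(tabulate(labels, k), decreasing = TRUE)
    labels <- match(labels, ord)
  }
  list(labels = setNames(as.integer(labels), ids), k = k,
       centers = km$centers, scaling = list(mean = mu, sd = sdv))
}

#' Welch power spectral density, averaged per cluster
#'
#' Mean of Hann-windowed periodograms over 50%-overlapping segments
#' (default length 256 samples), averaged across the cells of each cluster.
#'
#' @param traces cells x time matrix of conditioned traces
#' @param labels cluster label per cell
#' @param rateHz sampling rate, Hz
#' @param segLength segment length in samples
#' @return data.frame with `freq_hz`, one `cluster_<k>` column per cluster
#' @export
clusterPSD <- function(traces, labels, rateHz = 1.03, segLength = 256L) {
  n <- ncol(traces)
  segLength <- min(segLength, n)
  hop <- max(1L, segLength %/% 2L)
  win <- signal::hanning(segLength)
  starts <- seq(1L, n - segLength + 1L, by = hop)
  psdOne <- function(x) {
    ps <- vapply(starts, function(s) {
      seg <- (x[s:(s + segLength - 1L)] -
                mean(x[s:(s + segLength - 1L)])) * win
      Mod(fft(seg))^2 / (sum(win^2) * rateHz)
    }, numeric(segLength))
    rowMeans(as.matrix(ps))[seq_len(segLength %/% 2L + 1L)]
  }
  freq <- (seq_len(segLength %/% 2L + 1L) - 1L) * rateHz / segLength
  out <- data.frame(freq_hz = freq)
  for (cl in sort(unique(labels))) {
    sub <- traces[labels == cl, , drop = FALSE]
    out[[paste0("cluster_", cl)]] <-
      rowMeans(apply(sub, 1L, psdOne))
  }
  out
}

#' Chi-square association between cluster and niche
#'
#' Pearson chi-square (no continuity correction) on the niche x cluster
#' contingency table. Expected counts are returned; a zero expected count
#' aborts with advice to use an exact test.
#'
#' @param labels cluster assignment per cell
#' @param niche niche label per cell (same order)
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`
#' @export
associationTest <- function(labels, niche) {
  tab <- table(niche, labels)
  if (any(dim(tab) < 2L))
    stop("degenerate contingency table: use an exact test instead")
  exp0 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp0 == 0))
    stop("zero expected count: use Fisher's exact test instead")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, observed = tab, expected = ct$expected)
}
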