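# Movie conditioning: Fourier-domain rigid registration, temporal block
# downsampling, and per-cell dF/F0 extraction.

# 2-D cross-power spectrum peak -> translational shift of `moving` relative
# to `ref` (b[i,j] ~= a[i-dy, j-dx] gives c(dy, dx)). `upsample` > 1 refines
# the estimate on a local matrix-multiply DFT grid (subpixel).
phaseCorrShift <- function(ref, moving, upsample = 1) {
  stopifnot(all(dim(ref) == dim(moving)))
  n1 <- nrow(ref); n2 <- ncol(ref)
  if (all(moving == 0) || all(ref == 0)) {
    warning("all-zero frame: shift set to 0")
    return(c(0, 0))
  }
  Fa <- fft(ref); Fb <- fft(moving)
  R <- Fa * Conj(Fb)
  Rn <- R / pmax(Mod(R), .Machine$double.eps)
  # if moving = ref shifted by (dy, dx), the correlation peak sits at
  # position (-dy, -dx) modulo the array size
  cc <- Re(fft(Rn, inverse = TRUE)) / (n1 * n2)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  wrap <- function(i, n) { s <- i - 1L; if (s > n %/% 2) s - n else s }
  uy <- wrap(pk[1L], n1); ux <- wrap(pk[2L], n2)
  if (upsample > 1) {
    # evaluate |cc| on a fine grid around the integer peak (matrix DFT)
    gridR <- uy + seq(-1, 1, by = 1 / upsample)
    gridC <- ux + seq(-1, 1, by = 1 / upsample)
    fr <- c(0:floor((n1 - 1) / 2), -(n1 - floor((n1 - 1) / 2) - 1):-1)
    fc <- c(0:floor((n2 - 1) / 2), -(n2 - floor((n2 - 1) / 2) - 1):-1)
    Kr <- exp(2i * pi * outer(gridR, fr) / n1)
    Kc <- exp(2i * pi * outer(fc, gridC) / n2)
    ccUp <- Mod(Kr %*% Rn %*% Kc)
    pu <- which(ccUp == max(ccUp), arr.ind = TRUE)[1L, ]
    uy <- gridR[pu[1L]]; ux <- gridC[pu[2L]]
  }
  c(-uy, -ux)
}

#' Rigid (translational) motion correction by phase correlation
#'
#' Estimates each frame's translation against a reference frame from the
#' discrete-Fourier-domain cross-power spectrum and shifts the frame back.
#' Shifts are applied as rounded integer translations with replicate padding;
#' the returned shift table keeps the (optionally subpixel) estimates.
#'
#' @param movie an [ImagingMovie-class]
#' @param referenceFrame frame index to register against; `NULL` uses the
#'   temporal median image of the registration channel
#' @param channel channel used to estimate shifts (applied to all channels)
#' @param upsample subpixel refinement factor (1 = integer shifts)
#' @return list with `movie` (registered) and `shifts` (frames x 2 matrix of
#'   estimated (dy, dx) displacements of each frame; the applied correction
#'   is their negative)
#' @export
registerRigid <- function(movie, referenceFrame = NULL, channel = 1L,
                          upsample = 1) {
  stopifnot(is(movie, "ImagingMovie"))
  arr <- channelData(movie, channel)
  nT <- dim(arr)[3L]
  if (nT < 2L) stop("registration needs at least 2 frames")
  ref <- if (is.null(referenceFrame)) {
    apply(arr, c(1L, 2L), median)
  } else {
    stopifnot(referenceFrame >= 1L, referenceFrame <= nT)
    arr[, , referenceFrame]
  }
  shifts <- matrix(0, nT, 2L, dimnames = list(NULL, c("dy", "dx")))
  for (t in seq_len(nT))
    shifts[t, ] <- phaseCorrShift(ref, arr[, , t], upsample = upsample)
  out <- lapply(movie@channels, function(ch) {
    for (t in seq_len(nT))
      ch[, , t] <- translateMatrix(ch[, , t], -round(shifts[t, 1L]),
                                   -round(shifts[t, 2L]))
    ch
  })
  list(movie = imagingMovie(out, pixelSizeUm = movie@pixelSizeUm,
                            frameRateHz = movie@frameRateHz),
       shifts = shifts)
}

#' Temporal downsampling by non-overlapping block averaging
#'
#' Averages `round(sourceRate / targetRate)` consecutive frames (or samples)
#' into one. Works on an [ImagingMovie-class], a 3-D array, a matrix of
#' traces (time in columns), or a numeric vector. The effective output rate
#' `sourceRate / block` is recorded in the `"rateHz"` attribute (or the
#' movie's `frameRateHz`).
#'
#' @param x object to downsample
#' @param targetRateHz target rate, Hz (default the 1.03 Hz analysis rate)
#' @param sourceRateHz source rate; taken from the movie when `x` is one
#' @return downsampled object of the same kind
#' @export
downsampleTemporal <- function(x, targetRateHz = 1.03, sourceRateHz = NULL) {
  if (is(x, "ImagingMovie")) {
    src <- x@frameRateHz
    if (targetRateHz >= src)
      stop("target rate must be below the source rate")
    block <- round(src / targetRateHz)
    chans <- lapply(x@channels, .blockAvgArray, block = block)
    return(imagingMovie(chans, pixelSizeUm = x@pixelSizeUm,
                        frameRateHz = src / block))
  }
  if (is.null(sourceRateHz)) stop("sourceRateHz required for plain data")
  if (targetRateHz >= sourceRateHz)
    stop("target rate must be below the source rate")
  block <- round(sourceRateHz / targetRateHz)
  out <- if (is.matrix(x)) {
    nb <- ncol(x) %/% block
    if (nb < 1L) stop("fewer samples than one block")
    sapply(seq_len(nb), function(b)
      rowMeans(x[, ((b - 1L) * block + 1L):(b * block), drop = FALSE]))
  } else if (length(dim(x)) == 3L) {
    .blockAvgArray(x, block)
  } else {
    nb <- length(x) %/% block
    if (nb < 1L) stop("fewer samples than one block")
    colMeans(matrix(x[seq_len(nb * block)], nrow = block))
  }
  attr(out, "rateHz") <- sourceRateHz / block
  out
}

.blockAvgArray <- function(arr, block) {
  nT <- dim(arr)[3L]
  nb <- nT %/% block
  if (nb < 1L) stop("fewer frames than one block")
  out <- array(0, dim = c(dim(arr)[1:2], nb))
  for (b in seq_len(nb))
    out[, , b] <- apply(arr[, , ((b - 1L) * block + 1L):(b * block),
                            drop = FALSE], c(1L, 2L), mean)
  out
}

#' Extract per-cell dF/F0 traces from a movie
#'
#' Averages the Ca2+ channel over each labelled cell mask per frame and
#' normalizes to a baseline F0. The default F0 is the 10th percentile of the
#' cell's full-recording trace; a sliding-window percentile is available for
#' drifting baselines. Cells with F0 <= 0 are excluded and reported.
#'
#' @param movie an [ImagingMovie-class] or 3-D array at the analysis rate
#' @param cellMasks integer label matrix (0 = background)
#' @param f0Method `"percentile"` (whole recording) or `"sliding"`
#' @param f0Quantile baseline quantile (default 0.1)
#' @param windowS sliding-window width in seconds (only for `"sliding"`)
#' @param channel Ca2+ channel role or index when `movie` is an ImagingMovie
#' @param rateHz sampling rate when `movie` is a plain array
#' @return a [DffTraces-class]
#' @export
computeDff <- function(movie, cellMasks, f0Method = c("percentile", "sliding"),
                       f0Quantile = 0.1, windowS = 120, channel = 1L,
                       rateHz = 1.03) {
  f0Method <- match.arg(f0Method)
  arr <- if (is(movie, "ImagingMovie")) {
    rateHz <- movie@frameRateHz
    channelData(movie, channel)
  } else movie
  stopifnot(all(dim(cellMasks) == dim(arr)[1:2]))
  ids <- sort(setdiff(unique(as.integer(cellMasks)), 0L))
  nT <- dim(arr)[3L]
  flat <- matrix(arr, ncol = nT)
  traces <- matrix(NA_real_, length(ids), nT,
                   dimnames = list(sprintf("c%03d", ids), NULL))
  for (k in seq_along(ids))
    traces[k, ] <- colMeans(flat[which(cellMasks == ids[k]), , drop = FALSE])
  excluded <- character(0)
  f0 <- numeric(length(ids))
  dff <- traces
  for (k in seq_along(ids)) {
    if (f0Method == "percentile") {
      f0k <- quantile(traces[k, ], f0Quantile, names = FALSE)
      f0[k] <- f0k
      if (f0k <= 0) { excluded <- c(excluded, rownames(traces)[k]); next }
      dff[k, ] <- (traces[k, ] - f0k) / f0k
    } else {
      w <- max(3L, round(windowS * rateHz))
      base <- vapply(seq_len(nT), function(t) {
        i0 <- max(1L, t - w %/% 2L); i1 <- min(nT, t + w %/% 2L)
        quantile(traces[k, i0:i1], f0Quantile, names = FALSE)
      }, numeric(1L))
      f0[k] <- median(base)
      if (any(base <= 0)) { excluded <- c(excluded, rownames(traces)[k]); next }
      dff[k, ] <- (traces[k, ] - base) / base
    }
  }
  keep <- !(rownames(traces) %in% excluded)
  if (length(excluded))
    message("excluded cells with F0 <= 0: ", paste(excluded, collapse = ", "))
  new("DffTraces", traces = dff[keep, , drop = FALSE], rateHz = rateHz,
      f0Method = sprintf("%s q=%.2f", f0Method, f0Quantile),
      f0 = f0[keep], excluded = excluded)
}

#' Read / write a multi-page TIFF movie channel
#'
#' Thin wrappers over the `tiff` package for one channel of a movie, stored
#' as one page per frame (float32).
#'
#' @param path TIFF file path
#' @return `readMovieTiff` returns a rows x cols x frames array.
#' @export
readMovieTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  arr
}

#' @rdname readMovieTiff
#' @param arr rows x cols x frames array with values in `[0, 1]` after
#'   division by `scale`
#' @param scale intensity divisor applied before writing
#' @export
writeMovieTiff <- function(arr, path, scale = max(arr, 1)) {
  pages <- lapply(seq_len(dim(arr)[3L]), function(t)
    pmin(pmax(arr[, , t] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
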