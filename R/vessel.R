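# Radon-transform vessel diametry: project the vessel ROI along its axis,
# measure the profile width at a fraction of its maximum, and normalize to
# the first frame.

# Radon projection of masked pixels: intensities integrated along the axis
# direction `angleDeg`, binned by (rounded) perpendicular offset.
.radonProfile <- function(frame, roi, angleDeg) {
  px <- which(roi, arr.ind = TRUE)
  if (!nrow(px)) stop("empty ROI")
  th <- angleDeg * pi / 180
  # axis direction (cos, sin) in (col, row); perpendicular offset u
  u <- -px[, 2L] * sin(th) + px[, 1L] * cos(th)
  bin <- round(u - min(u)) + 1L
  vals <- frame[px]
  prof <- vapply(seq_len(max(bin)), function(b) sum(vals[bin == b]),
                 numeric(1L))
  list(offset = seq_len(max(bin)) - 1L, intensity = prof)
}

#' Select the vessel-axis projection angle
#'
#' Scans axis angles 0-179 degrees and keeps the angle whose Radon
#' projection (integration along the axis) has maximal variance -- the
#' profile is sharpest when integrating along the vessel. Near-isotropic
#' ROIs, where no angle stands out, abort with advice to supply the angle
#' manually.
#'
#' @param frame image matrix (e.g. a mean or first frame)
#' @param roi logical ROI mask
#' @param angleStep search step, degrees
#' @return axis angle in degrees (0 = horizontal vessel)
#' @export
selectProjectionAngle <- function(frame, roi, angleStep = 1) {
  bg <- median(frame[roi])
  fr <- pmax(frame - bg, 0)
  angles <- seq(0, 180 - angleStep, by = angleStep)
  v <- vapply(angles, function(a) {
    pr <- .radonProfile(fr, roi, a)$intensity
    var(pr)
  }, numeric(1L))
  if ((max(v) - median(v)) < 0.2 * median(v))
    stop("ROI is near-isotropic: supply the projection angle manually")
  angles[which.max(v)]
}

#' Perpendicular Radon intensity profile of a vessel
#'
#' Background (the median of the ROI pixels, robust while the vessel fills
#' less than half the ROI) is subtracted, then pixel intensities are
#' integrated parallel to the vessel axis as a function of perpendicular
#' offset. A uniform tube of width w yields a top-hat profile of width w.
#'
#' @param frame image matrix
#' @param roi logical ROI mask
#' @param angleDeg vessel-axis angle, degrees
#' @param subtractBackground subtract the ROI median before projecting
#' @return list with `offset` (pixels) and `intensity`
#' @export
vesselProfile <- function(frame, roi, angleDeg, subtractBackground = TRUE) {
  if (!any(roi)) stop("empty ROI")
  fr <- if (subtractBackground) pmax(frame - median(frame[roi]), 0) else frame
  .radonProfile(fr, roi, angleDeg)
}

# width of a 1-D profile at `frac` of its maximum, with linear interpolation
# at the two crossings
.profileWidth <- function(offset, intensity, frac = 0.5) {
  m <- max(intensity)
  if (m <= 0) return(NA_real_)
  h <- frac * m
  above <- which(intensity >= h)
  i0 <- above[1L]; i1 <- above[length(above)]
  left <- if (i0 > 1L)
    offset[i0] - (intensity[i0] - h) /
      (intensity[i0] - intensity[i0 - 1L]) else offset[i0] - 0.5
  right <- if (i1 < length(intensity))
    offset[i1] + (intensity[i1] - h) /
      (intensity[i1] - intensity[i1 + 1L]) else offset[i1] + 0.5
  right - left
}

#' Normalized vessel-diameter time series
#'
#' Per-frame width of the perpendicular Radon profile at `widthFraction` of
#' its maximum (default full width at half maximum), divided by the frame-1
#' width so the series starts at exactly 1. Frames with an all-zero profile
#' are linearly interpolated from their neighbours and flagged.
#'
#' @param movie rows x cols x frames array of the vessel channel, or an
#'   [ImagingMovie-class] (its `"vessel"` channel is used)
#' @param roi logical ROI mask
#' @param angleDeg vessel-axis angle; `NULL` selects it automatically from
#'   the temporal mean image
#' @param widthFraction profile-height fraction defining the width
#' @param rateHz sampling rate (taken from the movie when available)
#' @param vesselId identifier stored in the trace
#' @return a [DiameterTrace-class]
#' @export
diameterTrace <- function(movie, roi, angleDeg = NULL, widthFraction = 0.5,
                          rateHz = 1.03, vesselId = "v1") {
  pixelSizeUm <- NA_real_
  if (is(movie, "ImagingMovie")) {
    rateHz <- movie@frameRateHz
    pixelSizeUm <- movie@pixelSizeUm
    arr <- channelData(movie, if ("vessel" %in% names(movie@channels))
      "vessel" else 1L)
  } else arr <- movie
  nT <- dim(arr)[3L]
  if (is.null(angleDeg))
    angleDeg <- selectProjectionAngle(apply(arr, c(1L, 2L), mean), roi)
  w <- numeric(nT)
  flagged <- integer(0)
  for (t in seq_len(nT)) {
    pr <- vesselProfile(arr[, , t], roi, angleDeg)
    w[t] <- .profileWidth(pr$offset, pr$intensity, widthFraction)
    if (is.na(w[t])) flagged <- c(flagged, t)
  }
  if (length(flagged)) {
    ok <- which(!is.na(w))
    if (!length(ok)) stop("no frame has a measurable vessel profile")
    w[flagged] <- stats::approx(ok, w[ok], xout = flagged, rule = 2)$y
  }
  if (w[1L] <= 0) stop("frame-1 reference width is not positive")
  new("DiameterTrace", vesselId = vesselId, normalized = w / w[1L],
      widthPx = w,
      widthUm = if (is.na(pixelSizeUm)) rep(NA_real_, nT) else
        w * pixelSizeUm,
      angleDeg = as.numeric(angleDeg), rateHz = rateHz,
      flaggedFrames = flagged)
}
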