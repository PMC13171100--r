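#' Simulation configuration for the synthetic-data module
#'
#' Holds the acquisition geometry and study conditions every synthetic
#' generator assumes: 0.49 um/pixel spatial resolution, 15.5 Hz acquisition
#' downsampled to 1.03 Hz for analysis. Defaults describe a typical meningeal
#' field of view with sparse (< 0.05 Hz) macrophage Ca2+ events.
#'
#' @slot pixelSizeUm spatial resolution, micrometres per pixel (default 0.49)
#' @slot acqRateHz acquisition frame rate, Hz (default 15.5)
#' @slot analysisRateHz analysis frame rate after downsampling, Hz (1.03)
#' @slot durationS recording duration, seconds
#' @slot fovShape field-of-view size in pixels (rows, cols)
#' @slot nCells number of macrophages in the field
#' @slot nicheFractions named fractions for perivascular / non_perivascular
#' @slot eventRatePerMin mean spontaneous Ca2+ event rate per cell, events/min
#' @slot seed integer seed making all derived outputs reproducible
#' @exportClass SimConfig
setClass("SimConfig", representation(
  pixelSizeUm = "numeric", acqRateHz = "numeric", analysisRateHz = "numeric",
  durationS = "numeric", fovShape = "integer", nCells = "integer",
  nicheFractions = "numeric", eventRatePerMin = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (!(object@acqRateHz > object@analysisRateHz &&
        object@analysisRateHz > 0))
    msg <- c(msg, "must have acqRateHz > analysisRateHz > 0")
  if (object@durationS < 0) msg <- c(msg, "durationS must be >= 0")
  if (length(object@fovShape) != 2L || any(object@fovShape < 1L))
    msg <- c(msg, "fovShape must be two positive integers")
  if (abs(sum(object@nicheFractions) - 1) > 1e-8)
    msg <- c(msg, "nicheFractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param pixelSizeUm,acqRateHz,analysisRateHz,durationS,fovShape,nCells,nicheFractions,eventRatePerMin,seed
#'   see the class slots
#' @return a validated `SimConfig`
#' @examples
#' cfg <- simConfig(durationS = 300, nCells = 6, seed = 1)
#' @export
simConfig <- function(pixelSizeUm = 0.49, acqRateHz = 15.5,
                      analysisRateHz = 1.03, durationS = 900,
                      fovShape = c(192L, 192L), nCells = 12L,
                      nicheFractions = c(perivascular = 0.26,
                                         non_perivascular = 0.74),
                      eventRatePerMin = 0.3, seed = 1L) {
  new("SimConfig", pixelSizeUm = pixelSizeUm, acqRateHz = acqRateHz,
      analysisRateHz = analysisRateHz, durationS = durationS,
      fovShape = as.integer(fovShape), nCells = as.integer(nCells),
      nicheFractions = nicheFractions, eventRatePerMin = eventRatePerMin,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@durationS, "s,",
      paste(object@fovShape, collapse = "x"), "px @",
      object@pixelSizeUm, "um/px,", object@acqRateHz, "->",
      object@analysisRateHz, "Hz,", object@nCells, "cells, seed",
      object@seed, "\n")
})

#' Multi-channel imaging movie
#'
#' A time-lapse fluorescence movie stored as one rows x cols x frames array
#' per channel. Channel roles name the biology: `"gcamp"` for the GCaMP
#' Ca2+ channel, `"vessel"` for the vascular tracer channel.
#'
#' @slot channels named list of 3-D numeric arrays (rows, cols, frames)
#' @slot pixelSizeUm micrometres per pixel
#' @slot frameRateHz frame rate in Hz
#' @exportClass ImagingMovie
setClass("ImagingMovie", representation(
  channels = "list", pixelSizeUm = "numeric", frameRateHz = "numeric"))

setValidity("ImagingMovie", function(object) {
  msg <- character()
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be > 0")
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  if (anyDuplicated(names(object@channels)))
    msg <- c(msg, "channel roles must be unique")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each channel must be a 3-D array")
  else if (length(dims) > 1L &&
           !all(vapply(dims, identical, TRUE, dims[[1L]])))
    msg <- c(msg, "all channels must share the same dimensions")
  if (length(msg)) msg else TRUE
})

#' Construct an [ImagingMovie-class]
#' @param channels named list of rows x cols x frames arrays
#' @param pixelSizeUm micrometres per pixel
#' @param frameRateHz frame rate, Hz
#' @return an `ImagingMovie`
#' @export
imagingMovie <- function(channels, pixelSizeUm = 0.49, frameRateHz = 15.5) {
  new("ImagingMovie", channels = channels, pixelSizeUm = pixelSizeUm,
      frameRateHz = frameRateHz)
}

#' @describeIn imagingMovie number of frames
#' @param movie an `ImagingMovie`
#' @export
nFrames <- function(movie) dim(movie@channels[[1L]])[3L]

#' @describeIn imagingMovie extract one channel's array by role or index
#' @param channel channel role (character) or index
#' @export
channelData <- function(movie, channel = 1L) movie@channels[[channel]]

setMethod("show", "ImagingMovie", function(object) {
  d <- dim(object@channels[[1L]])
  cat("ImagingMovie:", d[1L], "x", d[2L], "px,", d[3L], "frames @",
      object@frameRateHz, "Hz; channels:",
      paste(names(object@channels), collapse = ", "), "\n")
})

#' Per-cell dF/F0 traces
#'
#' Baseline-normalized fluorescence `(F - F0)/F0` per cell at the analysis
#' rate, with a record of how F0 was defined.
#'
#' @slot traces cells x time numeric matrix, rownames are cell ids
#' @slot rateHz sampling rate, Hz
#' @slot f0Method description of the baseline definition
#' @slot f0 per-cell baseline fluorescence values
#' @slot excluded ids of cells dropped because F0 <= 0
#' @exportClass DffTraces
setClass("DffTraces", representation(
  traces = "matrix", rateHz = "numeric", f0Method = "character",
  f0 = "numeric", excluded = "character"))

setValidity("DffTraces", function(object) {
  msg <- character()
  if (object@rateHz <= 0) msg <- c(msg, "rateHz must be > 0")
  if (nrow(object@traces) && !all(is.finite(object@traces)))
    msg <- c(msg, "traces must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DffTraces", function(object) {
  cat("DffTraces:", nrow(object@traces), "cells x", ncol(object@traces),
      "samples @", object@rateHz, "Hz; F0:", object@f0Method, "\n")
})

#' @rdname DffTraces-class
#' @param x a `DffTraces`
#' @return `dffMatrix` returns the cells x time matrix.
#' @export
dffMatrix <- function(x) x@traces

#' Detected spatiotemporal Ca2+ events
#'
#' One row per event with onset/offset timing, footprint morphology
#' (area, perimeter, circularity), peak dF/F0, and the propagation label.
#' Footprint masks and per-pixel onset-time maps are retained alongside the
#' table for events that came from a movie (they are dropped by CSV I/O).
#'
#' @slot table data.frame with columns event_id, cell_id, t0_s, t1_s,
#'   duration_s, area_um2, perimeter_um, circularity, max_dff, propagating
#' @slot footprints optional list of logical footprint matrices per event
#' @slot onsetMaps optional list of per-pixel onset-time matrices (seconds,
#'   NA outside the footprint)
#' @slot pixelSizeUm micrometres per pixel of the source movie (NA if unknown)
#' @exportClass CalciumEvents
setClass("CalciumEvents", representation(
  table = "data.frame", footprints = "list", onsetMaps = "list",
  pixelSizeUm = "numeric"))

.eventCols <- c("event_id", "cell_id", "t0_s", "t1_s", "duration_s",
                "area_um2", "perimeter_um", "circularity", "max_dff",
                "propagating")

setValidity("CalciumEvents", function(object) {
  tb <- object@table
  msg <- character()
  miss <- setdiff(.eventCols, names(tb))
  if (length(miss))
    return(paste("missing event column(s):", paste(miss, collapse = ", ")))
  if (nrow(tb)) {
    bad <- which(!(tb$t1_s > tb$t0_s))
    if (length(bad))
      msg <- c(msg, paste0("t1_s must exceed t0_s (row ",
                           paste(tb$event_id[bad], collapse = ","), ")"))
    bad <- which(tb$duration_s < 1 - 1e-9)
    if (length(bad))
      msg <- c(msg, paste0("duration_s below the 1-s minimum (row ",
                           paste(tb$event_id[bad], collapse = ","), ")"))
    if (!all(is.finite(tb$max_dff)))
      msg <- c(msg, "max_dff must be finite")
    if (any(tb$area_um2 <= 0)) msg <- c(msg, "area_um2 must be > 0")
    # epsilon allows digital-perimeter error on small footprints
    if (any(tb$circularity <= 0 | tb$circularity > 1.15))
      msg <- c(msg, "circularity must lie in (0, 1 + eps]")
    if (!all(tb$propagating %in% c("propagating", "stationary")))
      msg <- c(msg, "propagating must be 'propagating' or 'stationary'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [CalciumEvents-class] container
#' @param table event table (see class slots for the schema)
#' @param footprints,onsetMaps optional per-event spatial maps
#' @param pixelSizeUm source pixel size (um)
#' @return a validated `CalciumEvents`
#' @export
calciumEvents <- function(table, footprints = list(), onsetMaps = list(),
                          pixelSizeUm = NA_real_) {
  new("CalciumEvents", table = table, footprints = footprints,
      onsetMaps = onsetMaps, pixelSizeUm = pixelSizeUm)
}

#' @rdname CalciumEvents-class
#' @param x a `CalciumEvents`
#' @return `eventTable` returns the event data.frame.
#' @export
eventTable <- function(x) x@table

#' @rdname CalciumEvents-class
#' @export
nEvents <- function(x) nrow(x@table)

setMethod("show", "CalciumEvents", function(object) {
  cat("CalciumEvents:", nrow(object@table), "events in",
      length(unique(object@table$cell_id)), "cells\n")
})

#' Normalized vessel diameter time series
#'
#' Per-frame vessel width from the perpendicular Radon profile, divided by
#' the frame-1 width so the first sample is exactly 1.
#'
#' @slot vesselId vessel identifier
#' @slot normalized per-frame normalized diameter (frame 1 == 1)
#' @slot widthPx absolute per-frame width, pixels
#' @slot widthUm absolute per-frame width, micrometres (NA if unknown scale)
#' @slot angleDeg vessel-axis projection angle, degrees
#' @slot rateHz sampling rate, Hz
#' @slot flaggedFrames frames whose profile was empty and was interpolated
#' @exportClass DiameterTrace
setClass("DiameterTrace", representation(
  vesselId = "character", normalized = "numeric", widthPx = "numeric",
  widthUm = "numeric", angleDeg = "numeric", rateHz = "numeric",
  flaggedFrames = "integer"))

setValidity("DiameterTrace", function(object) {
  msg <- character()
  if (length(object@normalized)) {
    if (abs(object@normalized[1L] - 1) > 1e-12)
      msg <- c(msg, "frame-1 normalized diameter must equal 1")
    if (any(object@normalized <= 0))
      msg <- c(msg, "normalized diameters must be > 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiameterTrace", function(object) {
  cat("DiameterTrace", object@vesselId, ":", length(object@normalized),
      "frames @", object@rateHz, "Hz, axis", round(object@angleDeg, 1),
      "deg, range", paste(round(range(object@normalized), 3),
                          collapse = "-"), "\n")
})

#' @rdname DiameterTrace-class
#' @param x a `DiameterTrace`
#' @return `normalizedDiameter` returns the normalized series.
#' @export
normalizedDiameter <- function(x) x@normalized

#' Two-state Gaussian locomotion HMM
#'
#' Emission and transition parameters of the rest/run hidden Markov model
#' fitted to wheel-encoder speed. State 2 ("run") always has the larger
#' emission mean.
#'
#' @slot means per-state emission means, cm/s (rest, run)
#' @slot sds per-state emission standard deviations
#' @slot transMat 2x2 transition probability matrix (rows sum to 1)
#' @slot initProb initial state distribution
#' @slot rateHz sampling rate the model was trained at
#' @slot logLik final training log-likelihood
#' @exportClass LocomotionModel
setClass("LocomotionModel", representation(
  means = "numeric", sds = "numeric", transMat = "matrix",
  initProb = "numeric", rateHz = "numeric", logLik = "numeric"))

setValidity("LocomotionModel", function(object) {
  msg <- character()
  if (length(object@means) != 2L || object@means[2L] <= object@means[1L])
    msg <- c(msg, "run-state mean must exceed rest-state mean")
  if (any(object@sds <= 0)) msg <- c(msg, "emission sds must be > 0")
  if (any(abs(rowSums(object@transMat) - 1) > 1e-6))
    msg <- c(msg, "transition rows must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocomotionModel", function(object) {
  cat("LocomotionModel: rest ", round(object@means[1L], 2), " / run ",
      round(object@means[2L], 2), " cm/s; P(rest->run)=",
      round(object@transMat[1L, 2L], 4), ", P(run->rest)=",
      round(object@transMat[2L, 1L], 4), "\n", sep = "")
})

#' Decoded locomotion states and bouts
#'
#' @slot states per-sample state: 0 = rest, 1 = run
#' @slot rateHz sampling rate, Hz
#' @slot bouts data.frame of run bouts (start_s, end_s, duration_s),
#'   non-overlapping and sorted
#' @exportClass LocomotionStates
setClass("LocomotionStates", representation(
  states = "integer", rateHz = "numeric", bouts = "data.frame"))

setValidity("LocomotionStates", function(object) {
  msg <- character()
  if (length(object@states) && !all(object@states %in% c(0L, 1L)))
    msg <- c(msg, "states must be 0 (rest) or 1 (run)")
  b <- object@bouts
  if (nrow(b) > 1L && any(diff(b$start_s) <= 0))
    msg <- c(msg, "bouts must be sorted")
  if (nrow(b) > 1L && any(b$start_s[-1L] < b$end_s[-nrow(b)]))
    msg <- c(msg, "bouts must not overlap")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocomotionStates", function(object) {
  cat("LocomotionStates:", length(object@states), "samples @",
      object@rateHz, "Hz;", nrow(object@bouts), "bouts, run fraction",
      round(mean(object@states == 1L), 3), "\n")
})

#' @rdname LocomotionStates-class
#' @param x a `LocomotionStates`
#' @return `stateVector` returns the 0/1 state vector; `bouts` the bout table.
#' @export
stateVector <- function(x) x@states

#' @rdname LocomotionStates-class
#' @export
bouts <- function(x) x@bouts

#' Fitted lagged elastic-net GLM
#'
#' Result of regressing a response series on a +/-60 s lagged copy bank of a
#' predictor series with a Gaussian elastic-net GLM (alpha = 0.01, penalty by
#' 10-fold cross-validation on the first 75% of samples). Deviance explained
#' is evaluated on the held-out final 25%; fits at or above 0.1 are flagged
#' well-fit.
#'
#' @slot coefficients per-lag coefficients (standardized predictor scale)
#' @slot lagsS lag grid in seconds (negative = predictor follows response)
#' @slot alpha elastic-net mixing parameter
#' @slot lambda penalty chosen by cross-validation
#' @slot devTrain,devTest deviance explained on train / held-out test block
#' @slot wellFit logical, devTest >= 0.1
#' @slot peakSign sign of the coefficient at the largest |coefficient| lag
#' @slot comDelayS |coefficient|-weighted centre-of-mass delay, seconds
#' @slot flags character vector of quality flags
#' @slot standardization record of the train-set column statistics used
#' @exportClass LaggedGLMFit
setClass("LaggedGLMFit", representation(
  coefficients = "numeric", lagsS = "numeric", alpha = "numeric",
  lambda = "numeric", devTrain = "numeric", devTest = "numeric",
  wellFit = "logical", peakSign = "character", comDelayS = "numeric",
  flags = "character", standardization = "list"))

setValidity("LaggedGLMFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@lagsS))
    msg <- c(msg, "one coefficient per lag required")
  if (is.finite(object@devTest) && object@devTest > 1 + 1e-9)
    msg <- c(msg, "deviance explained cannot exceed 1")
  if (is.finite(object@comDelayS) &&
      (object@comDelayS < min(object@lagsS) - 1e-9 ||
       object@comDelayS > max(object@lagsS) + 1e-9))
    msg <- c(msg, "centre-of-mass delay must lie inside the lag window")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LaggedGLMFit", function(object) {
  cat("LaggedGLMFit: dev(test) =", round(object@devTest, 3),
      if (object@wellFit) "(well fit)" else "(not well fit)",
      "; peak sign", object@peakSign, "; CoM delay",
      round(object@comDelayS, 2), "s\n")
})

#' @rdname LaggedGLMFit-class
#' @param x a `LaggedGLMFit`
#' @return `devianceExplained` returns the held-out deviance explained;
#'   `lagCoefficients` the per-lag coefficient vector named by lag (s).
#' @export
devianceExplained <- function(x) x@devTest

#' @rdname LaggedGLMFit-class
#' @export
lagCoefficients <- function(x) setNames(x@coefficients, x@lagsS)
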