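# Synthetic-data generators. Each generator plants the statistical structure
# the corresponding analysis stage assumes, and returns the ground truth so
# downstream recovery can be scored.

#' Simulate a two-state (rest/run) wheel-velocity trace
#'
#' Emits a Markov-switching Gaussian speed series: a hidden rest/run chain
#' with the given transition probabilities, plus white measurement noise on
#' the state-dependent mean speed.
#'
#' @param durationS trace duration, seconds
#' @param rateHz sampling rate, Hz (default the 1.03 Hz analysis rate)
#' @param pRestToRun,pRunToRest per-sample transition probabilities, in (0,1)
#' @param restMean,runMean state mean speeds, cm/s; `runMean > restMean >= 0`
#' @param noiseSd measurement noise SD, cm/s
#' @param seed integer seed (fixed seed gives identical output)
#' @return list with `time_s`, `speed` (cm/s) and the hidden `state`
#'   (0 = rest, 1 = run)
#' @examples
#' v <- makeVelocityTrace(60, 1.03, 0.02, 0.05, 0, 10, 0.5, seed = 1)
#' @export
makeVelocityTrace <- function(durationS, rateHz = 1.03, pRestToRun = 0.02,
                              pRunToRest = 0.05, restMean = 0, runMean = 10,
                              noiseSd = 0.5, seed = NULL) {
  for (nm in c("durationS", "rateHz", "pRestToRun", "pRunToRest",
               "restMean", "runMean", "noiseSd"))
    assertScalar(get(nm), nm)
  if (pRestToRun <= 0 || pRestToRun >= 1 || pRunToRest <= 0 || pRunToRest >= 1)
    stop("transition probabilities must lie strictly in (0, 1)")
  if (!(runMean > restMean && restMean >= 0))
    stop("need runMean > restMean >= 0")
  n <- floor(durationS * rateHz)
  if (n < 1L)
    return(list(time_s = numeric(0), speed = numeric(0), state = integer(0)))
  withSeed(seed, {
    state <- integer(n)
    # start from the stationary distribution of the 2-state chain
    pRun <- pRestToRun / (pRestToRun + pRunToRest)
    state[1L] <- rbinom(1L, 1L, pRun)
    u <- runif(n)
    for (t in seq_len(n - 1L)) {
      p <- if (state[t] == 0L) pRestToRun else 1 - pRunToRest
      state[t + 1L] <- as.integer(u[t] < p)
    }
    speed <- ifelse(state == 1L, runMean, restMean) + rnorm(n, 0, noiseSd)
    list(time_s = (seq_len(n) - 1L) / rateHz, speed = speed, state = state)
  })
}

#' Simulate a locomotion-coupled vessel-diameter trace
#'
#' `diameter = baseline * (1 + gain * state) + noise`. A negative gain
#' emulates the dural vasoconstriction seen during running bouts; a positive
#' gain emulates pial dilation. With `smoothS > 0` the binary state is first
#' smoothed with a moving average of that width to mimic sluggish vascular
#' kinetics (default 0: the coupling is instantaneous and the noiseless trace
#' dips by exactly `|gain|` during every run bout).
#'
#' @param states 0/1 locomotion state vector (see [makeVelocityTrace()])
#' @param gain fractional diameter change in the run state
#' @param baselineUm resting diameter, micrometres (> 0)
#' @param noiseSd additive noise SD in normalized units (fraction of baseline)
#' @param seed integer seed
#' @param rateHz sampling rate, Hz
#' @param smoothS moving-average width for the state, seconds
#' @return numeric vector of diameters (micrometres)
#' @export
makeCoupledDiameter <- function(states, gain, baselineUm, noiseSd = 0,
                                seed = NULL, rateHz = 1.03, smoothS = 0) {
  assertScalar(gain, "gain"); assertScalar(baselineUm, "baselineUm")
  assertScalar(noiseSd, "noiseSd")
  if (baselineUm <= 0) stop("baselineUm must be > 0")
  s <- as.numeric(states)
  if (smoothS > 0 && length(s) > 1L) {
    w <- max(1L, round(smoothS * rateHz))
    k <- rep(1 / w, w)
    s <- as.numeric(stats::filter(s, k, sides = 2))
    s[is.na(s)] <- as.numeric(states)[is.na(s)]
  }
  withSeed(seed,
    baselineUm * (1 + gain * s) + baselineUm * rnorm(length(s), 0, noiseSd))
}

#' Simulate a macrophage Ca2+ trace coupled to vessel diameter
#'
#' `trace = gain * (diameter shifted by lagS, mean-centred) + offset + noise`,
#' rectified at zero. The offset equals `-min(gain * centred diameter)` so
#' that in the noiseless case the trace is an exact affine function of the
#' (lagged) diameter and rectification never clips the signal component --
#' only noise excursions can be clipped.
#'
#' @param diameter vessel-diameter series (any units)
#' @param gain coupling gain (either sign; dF/F0 per normalized diameter)
#' @param lagS lag in seconds; positive means the Ca2+ trace follows the
#'   diameter. Must satisfy `|lagS| <= 60` (the GLM lag window).
#' @param noiseSd additive white-noise SD (dF/F0 units)
#' @param seed integer seed
#' @param rateHz sampling rate, Hz
#' @return numeric dF/F0 series the same length as `diameter`
#' @export
makeCoupledCaTrace <- function(diameter, gain, lagS = 0, noiseSd = 0,
                               seed = NULL, rateHz = 1.03) {
  assertScalar(gain, "gain"); assertScalar(lagS, "lagS")
  if (abs(lagS) > 60)
    stop("|lagS| must be <= 60 s (the GLM lag window)")
  d <- as.numeric(diameter) - mean(diameter)
  k <- round(lagS * rateHz)
  n <- length(d)
  shifted <- numeric(n)
  src <- seq_len(n) - k
  ok <- src >= 1L & src <= n
  shifted[ok] <- d[src[ok]]              # edges stay at the (zero) mean
  sig <- gain * shifted
  offset <- -min(sig)
  withSeed(seed, pmax(0, sig + offset + rnorm(n, 0, noiseSd)))
}

#' Plant ground truth for a synthetic field of view
#'
#' Draws per-cell niche labels and footprint shapes (rod-shaped perivascular
#' cells along the vessel, rounded non-perivascular cells), Poisson event
#' trains at the configured rate, per-event propagation labels, and a vessel
#' with locomotion coupling. If `csdRateRatios` is given, per-cell post/pre
#' rate ratios are planted strictly above 2, below 0.5, or inside [0.5, 2]
#' so the response class of every cell is unambiguous.
#'
#' @param config a [SimConfig-class]
#' @param propagProfile probabilities a cell is only-propagating, mixed, or
#'   only-stationary
#' @param csdRateRatios optional numeric vector (recycled over cells) of
#'   planted post/pre CSD rate ratios
#' @param tCsdS CSD onset time, seconds (used only with `csdRateRatios`)
#' @return list with `cells`, `events`, `vessel`, and optional `csd` entries
#' @export
generateGroundTruth <- function(config,
                                propagProfile = c(only_propagating = 0.90,
                                                  mixed = 0.05,
                                                  only_stationary = 0.05),
                                csdRateRatios = NULL, tCsdS = 1800) {
  stopifnot(is(config, "SimConfig"))
  withSeed(config@seed, {
    nc <- config@nCells
    niche <- sample(names(config@nicheFractions), nc, replace = TRUE,
                    prob = config@nicheFractions)
    shape <- ifelse(niche == "perivascular", "rod", "round")
    profile <- sample(names(propagProfile), nc, replace = TRUE,
                      prob = propagProfile)
    # centroids on a jittered grid, in micrometres
    fovUm <- config@fovShape * config@pixelSizeUm
    g <- ceiling(sqrt(nc))
    gx <- ((seq_len(nc) - 1L) %% g + 0.5) / g * fovUm[2L]
    gy <- ((seq_len(nc) - 1L) %/% g + 0.5) / g * fovUm[1L]
    cells <- data.frame(
      cell_id = sprintf("c%03d", seq_len(nc)), niche = niche, shape = shape,
      centroid_x_um = gx + runif(nc, -2, 2),
      centroid_y_um = gy + runif(nc, -2, 2),
      propag_profile = profile, stringsAsFactors = FALSE)
    ev <- vector("list", nc)
    for (i in seq_len(nc)) {
      k <- rpois(1L, config@eventRatePerMin * config@durationS / 60)
      if (k == 0L) next
      t0 <- sort(runif(k, 0, max(config@durationS - 12, 1)))
      dur <- pmin(pmax(stats::rlnorm(k, log(8), 0.35), 1.5),
                  config@durationS - t0)
      prop <- switch(cells$propag_profile[i],
                     only_propagating = rep(TRUE, k),
                     only_stationary = rep(FALSE, k),
                     mixed = {
                       z <- runif(k) < 0.5
                       if (k >= 2L) { z[1L] <- TRUE; z[2L] <- FALSE }
                       z
                     })
      ev[[i]] <- data.frame(
        cell_id = cells$cell_id[i], t0_s = t0, t1_s = t0 + dur,
        amplitude = runif(k, 0.5, 1.5), propagating = prop,
        direction_deg = runif(k, 0, 360), stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev)
    if (is.null(events))
      events <- data.frame(cell_id = character(), t0_s = numeric(),
                           t1_s = numeric(), amplitude = numeric(),
                           propagating = logical(), direction_deg = numeric())
    truth <- list(
      cells = cells, events = events,
      vessel = list(baseline_um = 20, gain = -0.10, noise_sd = 0.01))
    if (!is.null(csdRateRatios)) {
      rr <- rep_len(csdRateRatios, nc)
      cls <- ifelse(rr > 2, "increased", ifelse(rr < 0.5, "decreased",
                                                "unchanged"))
      truth$csd <- data.frame(cell_id = cells$cell_id, t_csd_s = tCsdS,
                              rate_ratio = rr, persistent_class = cls,
                              stringsAsFactors = FALSE)
    }
    truth
  })
}

# per-shape footprint morphology used by makeEventTable (areas inside the
# 125-750 um^2 detection window; rods are elongated, low circularity)
.shapeMorphology <- function(shape, pixelSizeUm) {
  if (shape == "rod") {
    lenUm <- runif(1L, 40, 60); widUm <- runif(1L, 4, 6)
    area <- lenUm * widUm
    perim <- 2 * (lenUm + widUm)
  } else {
    rUm <- runif(1L, 7, 12)
    area <- pi * rUm^2
    perim <- 2 * pi * rUm
  }
  c(area_um2 = area, perimeter_um = perim,
    circularity = min(4 * pi * area / perim^2, 1))
}

#' Generate a planted Ca2+ event table
#'
#' Produces the documented event-table schema directly from ground truth,
#' standing in for the event export of the detection stage. Morphology is
#' drawn per cell shape; timing and amplitude come from the planted events.
#'
#' @param config a [SimConfig-class]
#' @param truth output of [generateGroundTruth()] (generated from `config`
#'   when omitted)
#' @return a [CalciumEvents-class]
#' @export
makeEventTable <- function(config, truth = generateGroundTruth(config)) {
  ev <- truth$events
  if (nrow(ev)) {
    dup <- duplicated(ev[, c("cell_id", "t0_s")])
    if (any(dup))
      stop("overlapping same-cell events with identical onsets are ambiguous")
    if (any(ev$t1_s > config@durationS + 1e-9))
      stop("planted events extend beyond the movie duration")
  }
  shapes <- setNames(truth$cells$shape, truth$cells$cell_id)
  tb <- withSeed(config@seed + 1L, {
    morph <- t(vapply(seq_len(nrow(ev)), function(i)
      .shapeMorphology(shapes[[ev$cell_id[i]]], config@pixelSizeUm),
      numeric(3L)))
    data.frame(
      event_id = seq_len(nrow(ev)), cell_id = ev$cell_id,
      t0_s = ev$t0_s, t1_s = ev$t1_s, duration_s = ev$t1_s - ev$t0_s,
      area_um2 = if (nrow(ev)) morph[, "area_um2"] else numeric(0),
      perimeter_um = if (nrow(ev)) morph[, "perimeter_um"] else numeric(0),
      circularity = if (nrow(ev)) morph[, "circularity"] else numeric(0),
      max_dff = ev$amplitude,
      propagating = ifelse(ev$propagating, "propagating", "stationary"),
      stringsAsFactors = FALSE)
  })
  if (!nrow(ev))
    tb <- data.frame(event_id = integer(), cell_id = character(),
                     t0_s = numeric(), t1_s = numeric(),
                     duration_s = numeric(), area_um2 = numeric(),
                     perimeter_um = numeric(), circularity = numeric(),
                     max_dff = numeric(), propagating = character(),
                     stringsAsFactors = FALSE)
  calciumEvents(tb, pixelSizeUm = config@pixelSizeUm)
}

# difference-of-exponentials Ca2+ kernel, peak-normalized to 1
.eventKernel <- function(tS, riseS = 2, decayS = 8) {
  k <- exp(-tS / decayS) - exp(-tS / riseS)
  k[tS < 0] <- 0
  tPeak <- riseS * decayS / (decayS - riseS) * log(decayS / riseS)
  k / (exp(-tPeak / decayS) - exp(-tPeak / riseS))
}

# place rod / round footprints into a label matrix, avoiding collisions
.placeFootprints <- function(cells, fov, pixelSizeUm) {
  lab <- matrix(0L, fov[1L], fov[2L])
  for (i in seq_len(nrow(cells))) {
    cy <- round(cells$centroid_y_um[i] / pixelSizeUm)
    cx <- round(cells$centroid_x_um[i] / pixelSizeUm)
    if (cells$shape[i] == "rod") {
      hl <- round(25 / pixelSizeUm / 2); hw <- max(1L, round(5 / pixelSizeUm / 2))
      ri <- max(1, cy - hw):min(fov[1L], cy + hw)
      ci <- max(1, cx - hl):min(fov[2L], cx + hl)
      fp <- as.matrix(expand.grid(ri, ci))
    } else {
      r <- round(9 / pixelSizeUm)
      ri <- max(1, cy - r):min(fov[1L], cy + r)
      ci <- max(1, cx - r):min(fov[2L], cx + r)
      gr <- expand.grid(ri, ci)
      fp <- as.matrix(gr[(gr[, 1L] - cy)^2 + (gr[, 2L] - cx)^2 <= r^2, ])
    }
    if (any(lab[fp] != 0L)) {
      warning("footprint collision for ", cells$cell_id[i],
              "; cell re-placed")
      sh <- round(12 / pixelSizeUm)
      fp[, 1L] <- pmin(pmax(fp[, 1L] + sh, 1L), fov[1L])
      fp[, 2L] <- pmin(pmax(fp[, 2L] + sh, 1L), fov[2L])
    }
    lab[fp] <- i
  }
  lab
}

#' Render a two-channel synthetic movie with planted ground truth
#'
#' Channel `"gcamp"` holds cell footprints modulated by the planted event
#' time courses (difference-of-exponentials kernel, rise 2 s / decay 8 s);
#' propagating events get a linear onset-time gradient across the footprint
#' at the given propagation speed. Channel `"vessel"` holds a horizontal
#' vessel tube whose width follows `vesselWidthMod`. Optional integer rigid
#' jitter per frame is applied to both channels and recorded.
#'
#' @param config a [SimConfig-class]; the movie is rendered at the analysis
#'   rate
#' @param truth ground truth from [generateGroundTruth()]
#' @param noiseSd additive imaging noise SD (baseline units)
#' @param jitter optional frames x 2 integer matrix of (dy, dx) shifts
#' @param propagationSpeedUmS onset-gradient propagation speed, um/s
#' @param vesselWidthMod optional per-frame multiplicative width modulation
#'   (length = frame count), e.g. `1 + 0.1 * sin(...)`
#' @param baselineF baseline fluorescence level of cell pixels
#' @return list with `movie` ([ImagingMovie-class]), `cellMasks` (label
#'   matrix), `vesselMask` (logical matrix), the `truth`, and the applied
#'   `jitter`
#' @export
renderMovie <- function(config, truth = generateGroundTruth(config),
                        noiseSd = 0, jitter = NULL,
                        propagationSpeedUmS = 5, vesselWidthMod = NULL,
                        baselineF = 100) {
  fov <- config@fovShape
  rate <- config@analysisRateHz
  nT <- max(1L, floor(config@durationS * rate))
  lab <- .placeFootprints(truth$cells, fov, config@pixelSizeUm)
  # resting cells sit above the tissue background so frames carry static
  # anatomical contrast (what registration anchors on)
  gc <- array(0.2 * baselineF, dim = c(fov[1L], fov[2L], nT))
  gc[array(rep(lab > 0L, nT), dim = dim(gc))] <- baselineF
  tGrid <- (seq_len(nT) - 1L) / rate
  ev <- truth$events
  for (e in seq_len(nrow(ev))) {
    i <- match(ev$cell_id[e], truth$cells$cell_id)
    px <- which(lab == i, arr.ind = TRUE)
    if (!nrow(px)) next
    if (isTRUE(ev$propagating[e])) {
      th <- ev$direction_deg[e] * pi / 180
      proj <- (px[, 2L] * cos(th) + px[, 1L] * sin(th)) * config@pixelSizeUm
      delay <- (proj - min(proj)) / propagationSpeedUmS
    } else delay <- rep(0, nrow(px))
    for (p in seq_len(nrow(px))) {
      resp <- ev$amplitude[e] *
        .eventKernel(tGrid - (ev$t0_s[e] + delay[p]))
      resp[tGrid > ev$t1_s[e] + 20] <- 0   # truncate the tail well after t1
      gc[px[p, 1L], px[p, 2L], ] <- gc[px[p, 1L], px[p, 2L], ] +
        baselineF * resp
    }
  }
  # vessel: horizontal tube across the middle of the field
  w0 <- truth$vessel$baseline_um / config@pixelSizeUm
  mod <- if (is.null(vesselWidthMod)) rep(1, nT) else
    rep_len(vesselWidthMod, nT)
  vs <- array(10, dim = c(fov[1L], fov[2L], nT))
  midRow <- fov[1L] %/% 2
  rowOff <- abs(seq_len(fov[1L]) - midRow)
  for (t in seq_len(nT)) {
    # anti-aliased tube edge (1-px linear ramp) so profile widths
    # interpolate to subpixel accuracy
    edge <- pmin(pmax(mod[t] * w0 / 2 - rowOff + 0.5, 0), 1)
    vs[, , t] <- 10 + 190 * matrix(edge, fov[1L], fov[2L])
  }
  vesselMask <- matrix(rowOff <= w0 / 2, fov[1L], fov[2L])
  if (noiseSd > 0) withSeed(config@seed + 2L, {
    gc <- gc + array(rnorm(length(gc), 0, noiseSd), dim = dim(gc))
    vs <- vs + array(rnorm(length(vs), 0, noiseSd), dim = dim(vs))
  })
  if (!is.null(jitter)) {
    jitter <- matrix(as.integer(jitter), ncol = 2L)
    for (t in seq_len(nT)) {
      gc[, , t] <- translateMatrix(gc[, , t], jitter[t, 1L], jitter[t, 2L])
      vs[, , t] <- translateMatrix(vs[, , t], jitter[t, 1L], jitter[t, 2L])
    }
  }
  list(movie = imagingMovie(list(gcamp = gc, vessel = vs),
                            pixelSizeUm = config@pixelSizeUm,
                            frameRateHz = rate),
       cellMasks = lab, vesselMask = vesselMask, truth = truth,
       jitter = jitter)
}
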