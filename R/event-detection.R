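# Event-based Ca2+ signal detection: a documented z-threshold /
# connected-component detector with per-event morphology, onset-time maps,
# niche assignment, and propagation classification. This is a simplified,
# fully specified stand-in for machine-learning event segmentation platforms;
# their exports can be ingested directly with readEventTable().

#' Detection parameters
#'
#' Defaults mirror the target acquisition: 0.49 um/pixel, 1.03 Hz, 1-s minimum
#' event duration, and an event-size window of 523-3140 pixels
#' (125-750 um^2). Detection thresholds pixels at `zThreshold` robust
#' z-scores of their own temporal distribution (median/MAD).
#'
#' @param pixelSizeUm micrometres per pixel
#' @param rateHz analysis frame rate, Hz
#' @param minDurationS minimum event duration, seconds
#' @param sizeWindowPx footprint size window in pixels (low, high)
#' @param zThreshold robust z-score threshold (> 0)
#' @param onsetFraction per-pixel onset = first crossing of this fraction of
#'   the pixel's event peak
#' @param propagationDistanceUm minimum earliest-to-latest onset centroid
#'   separation for a propagating event
#' @return a named list of parameters
#' @export
detectionParams <- function(pixelSizeUm = 0.49, rateHz = 1.03,
                            minDurationS = 1,
                            sizeWindowPx = c(523, 3140), zThreshold = 3,
                            onsetFraction = 0.5,
                            propagationDistanceUm = 5) {
  stopifnot(sizeWindowPx[1L] < sizeWindowPx[2L], zThreshold > 0)
  list(pixelSizeUm = pixelSizeUm, rateHz = rateHz,
       minDurationS = minDurationS, sizeWindowPx = sizeWindowPx,
       zThreshold = zThreshold, onsetFraction = onsetFraction,
       propagationDistanceUm = propagationDistanceUm)
}

# 26-connected component labelling of a logical 3-D array via union-find
.label3d26 <- function(active) {
  d <- dim(active)
  idx <- which(active)
  if (!length(idx)) return(list(labels = integer(0), voxels = idx))
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 1L] != 0 | offs[, 2L] != 0 | offs[, 3L] != 0, ]
  # forward half only: each neighbour pair is visited once
  offs <- offs[offs[, 3L] > 0 | (offs[, 3L] == 0 & offs[, 2L] > 0) |
                 (offs[, 3L] == 0 & offs[, 2L] == 0 & offs[, 1L] > 0), ]
  co <- arrayInd(idx, d)
  for (o in seq_len(nrow(offs))) {
    ni <- co[, 1L] + offs[o, 1L]
    nj <- co[, 2L] + offs[o, 2L]
    nk <- co[, 3L] + offs[o, 3L]
    ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
      nk >= 1L & nk <= d[3L]
    if (!any(ok)) next
    nid <- id[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- which(nid > 0L)
    a <- which(ok)[hit]; b <- nid[hit]
    for (p in seq_along(a)) {
      ra <- findRoot(a[p]); rb <- findRoot(b[p])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), findRoot, integer(1L))
  list(labels = match(roots, unique(roots)), voxels = idx)
}

# perimeter of a footprint mask: boundary polygon through boundary-pixel
# centres (EBImage::ocontour), lightly smoothed, plus pi for the half-pixel
# centre-to-edge offset; single pixel gets 4 by convention
.maskPerimeter <- function(mask, smoothW = 5L) {
  if (sum(mask) == 1L) return(structure(4, flagged = TRUE))
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))[[1L]]
  n <- nrow(oc)
  if (n < 2L) return(structure(4, flagged = TRUE))
  if (n > smoothW) {
    pad <- (smoothW - 1L) %/% 2L
    sm <- apply(oc, 2L, function(v) {
      vp <- c(tail(v, pad), v, head(v, pad))
      as.numeric(stats::filter(vp, rep(1 / smoothW, smoothW)))[
        (pad + 1L):(pad + n)]
    })
  } else sm <- oc
  d <- sqrt(rowSums((sm - sm[c(2:n, 1L), , drop = FALSE])^2))
  sum(d) + pi
}

#' Morphological and intensity features of one event footprint
#'
#' Area is the pixel count times the squared pixel size; perimeter is the
#' smoothed boundary-contour length; circularity is `4*pi*area/perimeter^2`
#' (1 for a perfect disk). Duration spans first to last active frame
#' inclusively.
#'
#' @param footprint logical matrix marking the event's spatial footprint
#' @param dffValues dF/F0 values over the event's voxels (for the peak)
#' @param pixelSizeUm micrometres per pixel
#' @param frameRange first and last active frame index
#' @param rateHz frame rate, Hz
#' @return list with `area_um2`, `perimeter_um`, `circularity`,
#'   `duration_s`, `max_dff`, and `flagged` (single-pixel convention)
#' @export
eventFeatures <- function(footprint, dffValues, pixelSizeUm = 0.49,
                          frameRange = c(1L, 1L), rateHz = 1.03) {
  npx <- sum(footprint)
  if (npx < 1L) stop("empty footprint")
  perimPx <- .maskPerimeter(footprint)
  area <- npx * pixelSizeUm^2
  perim <- as.numeric(perimPx) * pixelSizeUm
  list(area_um2 = area, perimeter_um = perim,
       circularity = 4 * pi * area / perim^2,
       duration_s = (frameRange[2L] - frameRange[1L] + 1L) / rateHz,
       max_dff = max(dffValues),
       flagged = isTRUE(attr(perimPx, "flagged")))
}

#' Classify an event as propagating or stationary
#'
#' An event propagates when its per-pixel onset-time map shows (a) a maximum
#' pairwise onset lag of at least one frame and (b) a separation of at least
#' `minDistanceUm` between the centroids of the earliest-onset and
#' latest-onset pixels. Degenerate maps (all onsets equal) are stationary.
#'
#' @param onsetMap matrix of per-pixel onset times in seconds (NA outside
#'   the footprint)
#' @param pixelSizeUm micrometres per pixel
#' @param rateHz frame rate, Hz (one frame = 1/rateHz seconds)
#' @param minDistanceUm minimum onset-gradient extent, micrometres
#' @return `"propagating"` or `"stationary"`
#' @export
classifyPropagation <- function(onsetMap, pixelSizeUm = 0.49, rateHz = 1.03,
                                minDistanceUm = 5) {
  v <- onsetMap[!is.na(onsetMap)]
  if (!length(v)) stop("onset map is empty")
  lag <- max(v) - min(v)
  if (lag < 1 / rateHz - 1e-9) return("stationary")
  early <- which(onsetMap == min(v), arr.ind = TRUE)
  late <- which(onsetMap == max(v), arr.ind = TRUE)
  dist <- sqrt(sum((colMeans(early) - colMeans(late))^2)) * pixelSizeUm
  if (dist >= minDistanceUm) "propagating" else "stationary"
}

#' Detect spatiotemporal Ca2+ events in a dF/F0 movie
#'
#' Per-pixel robust z-scoring (median / 1.4826 MAD over time) of the dF/F0
#' movie, thresholding at `params$zThreshold`, 26-connected spatiotemporal
#' component labelling, and filtering by the minimum duration and the
#' footprint size window. Surviving components get morphology features, a
#' per-pixel onset-time map (first crossing of `onsetFraction` of the
#' pixel's event peak), and a propagation label.
#'
#' @param dffMovie rows x cols x frames array of dF/F0 at the analysis rate
#' @param params a [detectionParams()] list
#' @return a [CalciumEvents-class] (cell ids are unassigned:
#'   see [assignEventsToCells()])
#' @export
detectEvents <- function(dffMovie, params = detectionParams()) {
  d <- dim(dffMovie)
  if (is.null(d) || length(d) != 3L) stop("dffMovie must be a 3-D array")
  if (prod(d) == 0L || all(dffMovie == 0))
    return(calciumEvents(.emptyEventTable(),
                         pixelSizeUm = params$pixelSizeUm))
  nT <- d[3L]
  flat <- matrix(dffMovie, ncol = nT)
  med <- apply(flat, 1L, median)
  sigma <- apply(flat, 1L, mad)           # already scaled by 1.4826
  if (all(sigma == 0) && all(flat == flat[, 1L]))
    stop("saturated movie: no temporal variation to threshold at z >= ",
         params$zThreshold)
  sigma <- pmax(sigma, 1e-12)
  z <- (flat - med) / sigma
  active <- array(z >= params$zThreshold, dim = d)
  lab <- .label3d26(active)
  if (!length(lab$voxels))
    return(calciumEvents(.emptyEventTable(),
                         pixelSizeUm = params$pixelSizeUm))
  co <- arrayInd(lab$voxels, d)
  rows <- list(); fps <- list(); oms <- list()
  eid <- 0L
  for (g in seq_len(max(lab$labels))) {
    sel <- lab$labels == g
    vox <- co[sel, , drop = FALSE]
    f0 <- min(vox[, 3L]); f1 <- max(vox[, 3L])
    durS <- (f1 - f0 + 1L) / params$rateHz
    if (durS < params$minDurationS) next
    fp <- matrix(FALSE, d[1L], d[2L])
    fp[unique(vox[, 1:2, drop = FALSE])] <- TRUE
    npx <- sum(fp)
    if (npx < params$sizeWindowPx[1L] || npx > params$sizeWindowPx[2L]) next
    vals <- dffMovie[cbind(vox)]
    feat <- eventFeatures(fp, vals, params$pixelSizeUm, c(f0, f1),
                          params$rateHz)
    # per-pixel onset: first active-range frame crossing onsetFraction of
    # the pixel's own event peak
    px <- which(fp, arr.ind = TRUE)
    om <- matrix(NA_real_, d[1L], d[2L])
    for (p in seq_len(nrow(px))) {
      tr <- dffMovie[px[p, 1L], px[p, 2L], f0:f1]
      cross <- which(tr >= params$onsetFraction * max(tr))[1L]
      om[px[p, 1L], px[p, 2L]] <- (f0 + cross - 2L) / params$rateHz
    }
    propag <- classifyPropagation(om, params$pixelSizeUm, params$rateHz,
                                  params$propagationDistanceUm)
    eid <- eid + 1L
    rows[[eid]] <- data.frame(
      event_id = eid, cell_id = NA_character_,
      t0_s = (f0 - 1L) / params$rateHz, t1_s = f1 / params$rateHz,
      duration_s = durS, area_um2 = feat$area_um2,
      perimeter_um = feat$perimeter_um, circularity = feat$circularity,
      max_dff = feat$max_dff, propagating = propag,
      stringsAsFactors = FALSE)
    fps[[eid]] <- fp; oms[[eid]] <- om
  }
  if (!eid)
    return(calciumEvents(.emptyEventTable(),
                         pixelSizeUm = params$pixelSizeUm))
  calciumEvents(do.call(rbind, rows), footprints = fps, onsetMaps = oms,
                pixelSizeUm = params$pixelSizeUm)
}

.emptyEventTable <- function() {
  data.frame(event_id = integer(), cell_id = character(), t0_s = numeric(),
             t1_s = numeric(), duration_s = numeric(), area_um2 = numeric(),
             perimeter_um = numeric(), circularity = numeric(),
             max_dff = numeric(), propagating = character(),
             stringsAsFactors = FALSE)
}

#' Assign events to cells and label perivascular niches
#'
#' Each event goes to the cell whose mask maximally overlaps its footprint
#' (events overlapping no cell are kept with `cell_id = "unassigned"`). A
#' cell is perivascular when the minimum distance from its mask to the
#' vessel mask is at most `perivascularDistanceUm` (touching counts).
#'
#' @param events a [CalciumEvents-class] with footprints
#' @param cellMasks integer label matrix of cell footprints
#' @param vesselMask logical matrix of vessel pixels
#' @param perivascularDistanceUm niche distance threshold, micrometres
#' @param pixelSizeUm micrometres per pixel
#' @return list with `cells` (data.frame: cell_id, niche, centroid,
#'   n_events, event rate left NA until a window is chosen) and `events`
#'   (the input with cell ids filled in)
#' @export
assignEventsToCells <- function(events, cellMasks, vesselMask,
                                perivascularDistanceUm = 5,
                                pixelSizeUm = 0.49) {
  stopifnot(is(events, "CalciumEvents"))
  ids <- sort(setdiff(unique(as.integer(cellMasks)), 0L))
  # distance (px) from every pixel to the vessel mask
  dmap <- EBImage::distmap(matrix(as.numeric(!vesselMask), nrow(vesselMask)))
  cells <- data.frame(
    cell_id = sprintf("c%03d", ids),
    niche = NA_character_, centroid_x_um = NA_real_, centroid_y_um = NA_real_,
    n_events = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    px <- which(cellMasks == ids[k], arr.ind = TRUE)
    minDistUm <- min(dmap[px]) * pixelSizeUm
    cells$niche[k] <- if (minDistUm <= perivascularDistanceUm)
      "perivascular" else "non_perivascular"
    cells$centroid_y_um[k] <- mean(px[, 1L]) * pixelSizeUm
    cells$centroid_x_um[k] <- mean(px[, 2L]) * pixelSizeUm
  }
  tb <- events@table
  for (e in seq_len(nrow(tb))) {
    fp <- events@footprints[[e]]
    if (is.null(fp)) next
    ov <- table(cellMasks[fp & cellMasks > 0])
    if (!length(ov)) {
      tb$cell_id[e] <- "unassigned"
      message("event ", tb$event_id[e], " overlaps no cell; kept unassigned")
      next
    }
    best <- as.integer(names(ov)[which.max(ov)])
    tb$cell_id[e] <- sprintf("c%03d", best)
  }
  cnt <- table(tb$cell_id)
  cells$n_events <- as.integer(cnt[cells$cell_id])
  cells$n_events[is.na(cells$n_events)] <- 0L
  list(cells = cells,
       events = calciumEvents(tb, events@footprints, events@onsetMaps,
                              events@pixelSizeUm))
}

#' Event rate over a time window
#'
#' Count of events with onset in `[windowStartS, windowEndS)` divided by the
#' window length in minutes.
#'
#' @param events a [CalciumEvents-class], event data.frame, or numeric vector
#'   of onset times (s)
#' @param windowStartS,windowEndS window bounds in seconds
#' @return events per minute
#' @export
eventRate <- function(events, windowStartS, windowEndS) {
  if (windowEndS <= windowStartS)
    stop("windowEndS must exceed windowStartS")
  t0 <- if (is(events, "CalciumEvents")) events@table$t0_s
        else if (is.data.frame(events)) events$t0_s
        else as.numeric(events)
  sum(t0 >= windowStartS & t0 < windowEndS) /
    ((windowEndS - windowStartS) / 60)
}

#' Read / write the event-table CSV
#'
#' The schema is the documented ten-column event table (see
#' [CalciumEvents-class]); unknown extra columns are preserved on read and
#' written back. Rows violating the event invariants (e.g. `t1_s <= t0_s`)
#' raise an error naming the offending row.
#'
#' @param path CSV path
#' @return `readEventTable` returns a [CalciumEvents-class].
#' @export
readEventTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.eventCols, names(tb))
  if (length(miss))
    stop("event table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  tb$cell_id <- as.character(tb$cell_id)
  tb$propagating <- as.character(tb$propagating)
  calciumEvents(tb)
}

#' @rdname readEventTable
#' @param events a [CalciumEvents-class]
#' @export
writeEventTable <- function(events, path) {
  stopifnot(is(events, "CalciumEvents"))
  write.csv(events@table, path, row.names = FALSE)
  invisible(path)
}
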