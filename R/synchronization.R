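# Intercellular synchronization: temporally co-occurring event pairs across
# cells, their latency/duration/distance statistics, and interaction typing.

#' Find synchronized event pairs across cells
#'
#' Events in distinct cells are synchronous when their `[t0, t1]` intervals
#' overlap after symmetric dilation by `toleranceS`. Co-occurrences are
#' aggregated per unordered cell pair with the co-occurrence count, the mean
#' onset latency `t0_A - t0_B` (A the lexicographically smaller cell id),
#' the mean duration of the first-occurring event, and -- when centroids are
#' supplied -- the centroid distance.
#'
#' The sweep is a sorted interval join (events ordered by onset, candidate
#' window pruned by the running maximum offset), not an all-pairs scan.
#'
#' @param events a [CalciumEvents-class] or data.frame with `cell_id`,
#'   `t0_s`, `t1_s`
#' @param toleranceS overlap tolerance in seconds (>= 0, default 0)
#' @param centroids optional data.frame `cell_id`, `x_um`, `y_um`
#' @return data.frame: cellA, cellB, n_sync, mean_latency_s, first_dur_s,
#'   dist_um (NA without centroids)
#' @export
findSyncEvents <- function(events, toleranceS = 0, centroids = NULL) {
  stopifnot(toleranceS >= 0)
  tb <- if (is(events, "CalciumEvents")) events@table else events
  empty <- data.frame(cellA = character(), cellB = character(),
                      n_sync = integer(), mean_latency_s = numeric(),
                      first_dur_s = numeric(), dist_um = numeric(),
                      stringsAsFactors = FALSE)
  if (length(unique(tb$cell_id)) < 2L) return(empty)
  ord <- order(tb$t0_s)
  t0 <- tb$t0_s[ord] - toleranceS / 2
  t1 <- tb$t1_s[ord] + toleranceS / 2
  cid <- tb$cell_id[ord]
  n <- length(t0)
  rec <- list(); r <- 0L
  # sweep: for event i, scan forward while onsets can still overlap the
  # running maximum offset seen so far
  maxT1 <- cummax(t1)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && t0[j] <= maxT1[i]) {
      if (cid[i] != cid[j] && t0[j] <= t1[i] && t1[j] >= t0[i]) {
        a <- i; b <- j
        if (cid[b] < cid[a]) { a <- j; b <- i }
        first <- if (t0[i] <= t0[j]) i else j
        r <- r + 1L
        rec[[r]] <- data.frame(
          cellA = cid[a], cellB = cid[b],
          latency = (t0[a] - t0[b]),
          first_dur = t1[first] - t0[first] - toleranceS,
          stringsAsFactors = FALSE)
      }
      j <- j + 1L
    }
  }
  if (!r) return(empty)
  co <- do.call(rbind, rec)
  key <- paste(co$cellA, co$cellB, sep = "|")
  agg <- do.call(rbind, lapply(split(co, key), function(g)
    data.frame(cellA = g$cellA[1L], cellB = g$cellB[1L], n_sync = nrow(g),
               mean_latency_s = mean(g$latency),
               first_dur_s = mean(g$first_dur), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg$dist_um <- NA_real_
  if (!is.null(centroids)) {
    ix <- function(id) match(id, centroids$cell_id)
    agg$dist_um <- sqrt(
      (centroids$x_um[ix(agg$cellA)] - centroids$x_um[ix(agg$cellB)])^2 +
      (centroids$y_um[ix(agg$cellA)] - centroids$y_um[ix(agg$cellB)])^2)
  }
  agg[order(agg$cellA, agg$cellB), ]
}

#' Euclidean centroid distance between two cells
#'
#' @param cellA,cellB numeric length-2 centroids `(x_um, y_um)`
#' @return distance in micrometres
#' @export
pairDistance <- function(cellA, cellB) {
  sqrt(sum((as.numeric(cellA) - as.numeric(cellB))^2))
}

#' Regression of synchronization delay on pair distance
#'
#' Ordinary least squares of `|mean latency|` on centroid distance across
#' synchronized pairs; a flat relation (small R^2) indicates that spatial
#' proximity does not drive synchrony.
#'
#' @param pairs output of [findSyncEvents()] with `dist_um` populated
#' @return list with `slope`, `intercept`, `r_squared`, `n`
#' @export
distanceDelayRegression <- function(pairs) {
  ok <- complete.cases(pairs[, c("mean_latency_s", "dist_um")])
  if (sum(ok) < 3L) stop("need at least 3 pairs")
  x <- pairs$dist_um[ok]; y <- abs(pairs$mean_latency_s[ok])
  if (var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = sum(ok), flagged = TRUE))
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared), n = sum(ok),
       flagged = FALSE)
}

#' Regression of co-occurrence count on first-event duration
#'
#' Tests whether longer events trivially accumulate more simultaneous
#' partners: OLS of the pair's synchronous-event count on the mean duration
#' of the first-occurring event.
#'
#' @param pairs output of [findSyncEvents()]
#' @return list with `slope`, `intercept`, `r_squared`, `n`
#' @export
durationCountRegression <- function(pairs) {
  ok <- complete.cases(pairs[, c("first_dur_s", "n_sync")])
  if (sum(ok) < 3L) stop("need at least 3 pairs")
  x <- pairs$first_dur_s[ok]; y <- pairs$n_sync[ok]
  if (var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = sum(ok), flagged = TRUE))
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared), n = sum(ok),
       flagged = FALSE)
}

#' Type each cell's synchronization partners by niche
#'
#' Cells with at least one synchronous partner are categorized by the niche
#' composition of their partner set: only the same niche, only a different
#' niche, or mixed. Proportions are over the categorized cells and sum to 1.
#'
#' @param pairs output of [findSyncEvents()]
#' @param nicheLabels named character vector, cell id -> niche
#' @return list with `perCell` (data.frame cell_id, type) and `proportions`
#' @export
interactionTyping <- function(pairs, nicheLabels) {
  cells <- unique(c(pairs$cellA, pairs$cellB))
  if (!all(cells %in% names(nicheLabels)))
    stop("every synchronized cell needs a niche label")
  typeOf <- vapply(cells, function(cl) {
    partners <- c(pairs$cellB[pairs$cellA == cl],
                  pairs$cellA[pairs$cellB == cl])
    same <- nicheLabels[partners] == nicheLabels[cl]
    if (all(same)) "same_only" else if (!any(same)) "different_only"
    else "mixed"
  }, character(1L))
  perCell <- data.frame(cell_id = cells, type = typeOf,
                        stringsAsFactors = FALSE)
  props <- table(factor(typeOf,
                        levels = c("same_only", "different_only", "mixed")))
  list(perCell = perCell, proportions = props / max(sum(props), 1L))
}

#' Fraction of cells with at least one synchronized partner
#'
#' @param pairs output of [findSyncEvents()]
#' @param allCells character vector of every cell id in the field
#' @return fraction in `[0, 1]`
#' @export
coactiveFraction <- function(pairs, allCells) {
  length(unique(c(pairs$cellA, pairs$cellB))) / length(allCells)
}
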