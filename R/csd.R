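# CSD response analysis: phase windows around the depolarization, per-cell
# phase rates, rule-based acute/persistent classification, contingency
# summaries and group statistics.

#' Split a recording into CSD phase windows
#'
#' Half-open windows anchored at the CSD time: PreCSD `[tCsd - 30 min,
#' tCsd)`, DuringCSD `[tCsd, tCsd + 1 min)`, PostCSD `[tCsd + 1 min,
#' tCsd + 31 min)`. With the conventional anchor at 30 min this is
#' 0-30 / 30-31 / 31-61 min. Events are bucketed by onset time.
#'
#' @param events a [CalciumEvents-class] or data.frame with `t0_s`
#' @param tCsdS CSD onset, seconds (default 1800)
#' @param preMin,duringMin,postMin phase lengths, minutes
#' @param recordingDurationS total recording length; must cover the span
#' @return list with `windows` (data.frame phase/start_s/end_s) and the
#'   per-phase event subsets `pre`, `during`, `post`
#' @export
splitPhases <- function(events, tCsdS = 1800, preMin = 30, duringMin = 1,
                        postMin = 30,
                        recordingDurationS = tCsdS + (duringMin + postMin) * 60) {
  tb <- if (is(events, "CalciumEvents")) events@table else events
  w <- data.frame(
    phase = c("pre", "during", "post"),
    start_s = c(tCsdS - preMin * 60, tCsdS, tCsdS + duringMin * 60),
    end_s = c(tCsdS, tCsdS + duringMin * 60,
              tCsdS + (duringMin + postMin) * 60))
  if (w$start_s[1L] < 0)
    stop("pre window starts before the recording (tCsdS too small)")
  if (recordingDurationS < w$end_s[3L])
    stop("recording covers only ", recordingDurationS, " s but the phase ",
         "span ends at ", w$end_s[3L], " s")
  pick <- function(i) tb[tb$t0_s >= w$start_s[i] & tb$t0_s < w$end_s[i], ,
                         drop = FALSE]
  list(windows = w, pre = pick(1L), during = pick(2L), post = pick(3L))
}

#' Classify the persistent (PostCSD) response
#'
#' `increased` when the post rate strictly exceeds twice the pre rate,
#' `decreased` when strictly below half, otherwise `unchanged`; boundary
#' ratios are `unchanged`. A zero baseline classifies as `increased` for any
#' positive post rate and `unchanged` when both are zero (the rule the
#' strict inequalities imply at 0).
#'
#' @param preRate,postRate event rates, events/min (vectorized)
#' @return character vector in {increased, decreased, unchanged}
#' @export
classifyPersistent <- function(preRate, postRate) {
  stopifnot(all(preRate >= 0), all(postRate >= 0))
  ifelse(postRate > 2 * preRate, "increased",
         ifelse(postRate < 0.5 * preRate, "decreased", "unchanged"))
}

#' Classify the acute (DuringCSD) response
#'
#' `rule = "ratio"` (default): activated when the during-CSD rate strictly
#' exceeds twice the pre rate (with a zero baseline, any event during CSD
#' activates). `rule = "any_event"`: activated when at least one event
#' occurs during CSD -- justified by the near-absence of spontaneous events
#' within a 1-min window at baseline.
#'
#' @param preRate,duringRate event rates, events/min (vectorized)
#' @param rule classification rule
#' @return character vector in {activated, unchanged}
#' @export
classifyAcute <- function(preRate, duringRate,
                          rule = c("ratio", "any_event")) {
  rule <- match.arg(rule)
  stopifnot(all(preRate >= 0), all(duringRate >= 0))
  act <- if (rule == "ratio") duringRate > 2 * preRate else duringRate > 0
  ifelse(act, "activated", "unchanged")
}

#' Per-cell CSD response table
#'
#' Computes pre/during/post event rates per cell from a split recording and
#' applies both classification rules.
#'
#' @param events a [CalciumEvents-class] or event data.frame with `cell_id`,
#'   `t0_s`
#' @param cells data.frame with `cell_id` and `niche` (and optionally
#'   `treatment`)
#' @param tCsdS CSD onset, seconds
#' @param ... passed to [splitPhases()]
#' @return data.frame: cell_id, niche, pre_rate, during_rate, post_rate,
#'   acute, persistent, treatment
#' @export
csdResponses <- function(events, cells, tCsdS = 1800, ...) {
  ph <- splitPhases(events, tCsdS, ...)
  w <- ph$windows
  rateIn <- function(sub, i) vapply(cells$cell_id, function(cl)
    eventRate(sub$t0_s[sub$cell_id == cl], w$start_s[i], w$end_s[i]),
    numeric(1L))
  pre <- rateIn(ph$pre, 1L)
  dur <- rateIn(ph$during, 2L)
  post <- rateIn(ph$post, 3L)
  data.frame(
    cell_id = cells$cell_id, niche = cells$niche,
    pre_rate = pre, during_rate = dur, post_rate = post,
    acute = classifyAcute(pre, dur),
    persistent = classifyPersistent(pre, post),
    treatment = if ("treatment" %in% names(cells)) cells$treatment else
      NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Contingency summary of CSD response classes
#'
#' Counts and percentages (one decimal) of a response class split by a
#' grouping column, plus the pooled percentages and an association test:
#' Pearson chi-square when every expected count is at least 5, otherwise
#' Fisher's exact test.
#'
#' @param responses data.frame from [csdResponses()]
#' @param classColumn `"acute"` or `"persistent"` (or any factor column)
#' @param by grouping column, e.g. `"niche"` or `"treatment"`
#' @return list with `counts`, `percentages` (by group), `pooled`
#'   (percentage per class over all cells), `test` (htest) and `testUsed`
#' @export
summarizeContingency <- function(responses, classColumn = "persistent",
                                 by = "niche") {
  cls <- responses[[classColumn]]
  grp <- responses[[by]]
  keep <- !is.na(cls) & !is.na(grp)
  if (!all(keep)) warning("dropping ", sum(!keep), " unlabeled cells")
  cls <- cls[keep]; grp <- grp[keep]
  emptyGrp <- setdiff(unique(responses[[by]]), unique(grp))
  if (length(emptyGrp))
    warning("empty group(s) excluded: ", paste(emptyGrp, collapse = ", "))
  tab <- table(grp, cls)
  pct <- round(100 * prop.table(tab, margin = 1L), 1L)
  pooled <- round(100 * prop.table(table(cls)), 1L)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    test <- suppressWarnings(chisq.test(tab, correct = FALSE))
    used <- "chi-square"
  } else {
    test <- fisher.test(tab)
    used <- "fisher"
  }
  list(counts = tab, percentages = pct, pooled = pooled, test = test,
       testUsed = used)
}

#' Compare baseline rates between two groups (Mann-Whitney U)
#'
#' Two-sided rank-sum test with tie correction. Fully tied data (every value
#' identical across both groups) returns p = 1 by convention.
#'
#' @param groupA,groupB numeric rate vectors (at least one value each)
#' @return list with `U`, `p.value`, `nA`, `nB`
#' @export
compareBaselineRates <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
  if (length(unique(c(groupA, groupB))) == 1L)
    return(list(U = length(groupA) * length(groupB) / 2, p.value = 1,
                nA = length(groupA), nB = length(groupB)))
  ht <- suppressWarnings(wilcox.test(groupA, groupB, exact = NULL))
  list(U = unname(ht$statistic), p.value = ht$p.value,
       nA = length(groupA), nB = length(groupB))
}
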