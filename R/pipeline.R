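# Headless pipeline driver and table validation. A single YAML config (one
# section per stage) drives the run; the resolved config, a JSON manifest,
# and a text log are written next to the outputs so every artifact is
# reproducible from one root seed.

.defaultConfig <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, duration_s = 3660, n_cells = 24,
                    event_rate_per_min = 0.3, t_csd_s = 1800,
                    rate_ratio_increased = 3, rate_ratio_decreased = 0.25,
                    frac_increased = 0.22, frac_decreased = 0.59),
    detect = list(enabled = TRUE, events_csv = NULL),
    locomotion = list(enabled = TRUE, velocity_csv = NULL,
                      min_bout_s = 2),
    sync = list(enabled = TRUE, tolerance_s = 0),
    csd = list(enabled = TRUE, pre_min = 30, during_min = 1, post_min = 30))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order (simulate -> events ->
#' locomotion -> synchronization -> CSD classification), writing CSV/JSON
#' artifacts, a timestamped log, the resolved configuration, and a manifest
#' that marks which stages completed. With the synthetic stage enabled no
#' external inputs are needed; otherwise `detect$events_csv` (and optionally
#' `locomotion$velocity_csv`) must point at existing files.
#'
#' @param config a config list, a YAML file path, or `NULL` for defaults
#' @param outdir output directory (created if needed)
#' @param seed overrides the config seed when given
#' @return (invisibly) the manifest list; artifacts land in `outdir`
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("duraCa_run_"),
                        seed = NULL) {
  cfg <- .defaultConfig()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.list(config)) cfg <- modifyList(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logPath,
                               append = TRUE)
  manifest <- list(stages = list(), seed = cfg$seed)
  yaml::write_yaml(cfg, file.path(outdir, "resolved_config.yaml"))
  done <- function(stage, ok, files = character(0)) {
    manifest$stages[[stage]] <<- list(completed = ok, files = files)
    logLine("stage ", stage, if (ok) " completed" else " FAILED")
  }
  logLine("pipeline start, seed ", cfg$seed)

  events <- NULL; cells <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sc <- simConfig(durationS = cfg$simulate$duration_s,
                    nCells = cfg$simulate$n_cells,
                    eventRatePerMin = cfg$simulate$event_rate_per_min,
                    seed = cfg$seed)
    nC <- sc@nCells
    nInc <- round(cfg$simulate$frac_increased * nC)
    nDec <- round(cfg$simulate$frac_decreased * nC)
    rr <- rep(1, nC)
    rr[seq_len(nInc)] <- cfg$simulate$rate_ratio_increased
    if (nDec > 0) rr[nInc + seq_len(nDec)] <- cfg$simulate$rate_ratio_decreased
    truth <- generateGroundTruth(sc, csdRateRatios = rr,
                                 tCsdS = cfg$simulate$t_csd_s)
    truth <- .applyCsdSchedule(sc, truth)
    events <- makeEventTable(sc, truth)
    cells <- truth$cells
    writeEventTable(events, file.path(outdir, "events.csv"))
    write.csv(cells, file.path(outdir, "cells.csv"), row.names = FALSE)
    vel <- makeVelocityTrace(cfg$simulate$duration_s, 1.03,
                             seed = cfg$seed + 1L)
    write.csv(data.frame(time_s = vel$time_s, speed_cm_s = vel$speed),
              file.path(outdir, "velocity.csv"), row.names = FALSE)
    done("simulate", TRUE, c("events.csv", "cells.csv", "velocity.csv"))
  }
  if (isTRUE(cfg$detect$enabled) && is.null(events)) {
    path <- cfg$detect$events_csv
    if (is.null(path) || !file.exists(path)) {
      done("detect", FALSE)
      .writeManifest(manifest, outdir)
      stop("events CSV not found: ",
           if (is.null(path)) "(no path configured)" else path)
    }
    events <- readEventTable(path)
    cells <- data.frame(cell_id = unique(events@table$cell_id),
                        niche = "non_perivascular",
                        stringsAsFactors = FALSE)
    done("detect", TRUE, path)
  }
  if (isTRUE(cfg$locomotion$enabled)) {
    velPath <- file.path(outdir, "velocity.csv")
    if (!is.null(cfg$locomotion$velocity_csv))
      velPath <- cfg$locomotion$velocity_csv
    if (file.exists(velPath)) {
      vdf <- read.csv(velPath)
      model <- trainLocomotionHmm(vdf$speed_cm_s, rateHz = 1.03,
                                  seed = cfg$seed + 2L)
      st <- decodeStates(vdf$speed_cm_s, model)
      write.csv(data.frame(time_s = vdf$time_s, state = st@states),
                file.path(outdir, "states.csv"), row.names = FALSE)
      write.csv(st@bouts, file.path(outdir, "bouts.csv"), row.names = FALSE)
      done("locomotion", TRUE, c("states.csv", "bouts.csv"))
    } else done("locomotion", FALSE)
  }
  if (isTRUE(cfg$sync$enabled) && !is.null(events)) {
    pairs <- findSyncEvents(events, toleranceS = cfg$sync$tolerance_s)
    write.csv(pairs, file.path(outdir, "sync_pairs.csv"), row.names = FALSE)
    done("sync", TRUE, "sync_pairs.csv")
  }
  if (isTRUE(cfg$csd$enabled) && !is.null(events)) {
    resp <- csdResponses(events, cells, tCsdS = cfg$simulate$t_csd_s,
                         preMin = cfg$csd$pre_min,
                         duringMin = cfg$csd$during_min,
                         postMin = cfg$csd$post_min)
    write.csv(resp, file.path(outdir, "responses.csv"), row.names = FALSE)
    summ <- summarizeContingency(resp, "persistent", "niche")
    jsonlite::write_json(
      list(pooled = as.list(setNames(as.numeric(summ$pooled),
                                     names(summ$pooled))),
           test = summ$testUsed, p_value = summ$test$p.value),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    done("csd", TRUE, c("responses.csv", "summary.json"))
  }
  .writeManifest(manifest, outdir)
  logLine("pipeline end")
  invisible(manifest)
}

# replace the spontaneous post-CSD event trains with rate-ratio-scaled
# trains so planted CSD classes are exact in expectation
.applyCsdSchedule <- function(config, truth) {
  if (is.null(truth$csd)) return(truth)
  tCsd <- truth$csd$t_csd_s[1L]
  ev <- truth$events
  ev <- ev[ev$t0_s < tCsd, , drop = FALSE]     # keep pre events only
  postLen <- config@durationS - tCsd - 60
  base <- config@eventRatePerMin
  withSeed(config@seed + 3L, {
    newEv <- list()
    for (i in seq_len(nrow(truth$cells))) {
      cid <- truth$cells$cell_id[i]
      rr <- truth$csd$rate_ratio[truth$csd$cell_id == cid]
      k <- rpois(1L, base * rr * postLen / 60)
      if (k == 0L) next
      t0 <- sort(runif(k, tCsd + 60, config@durationS - 10))
      dur <- pmax(stats::rlnorm(k, log(8), 0.35), 1.5)
      newEv[[length(newEv) + 1L]] <- data.frame(
        cell_id = cid, t0_s = t0, t1_s = pmin(t0 + dur, config@durationS),
        amplitude = runif(k, 0.5, 1.5), propagating = TRUE,
        direction_deg = runif(k, 0, 360), stringsAsFactors = FALSE)
    }
    truth$events <- rbind(ev, do.call(rbind, newEv))
  })
  truth
}

.writeManifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

.tableSchemas <- list(
  events = list(
    required = c("event_id", "cell_id", "t0_s", "t1_s", "duration_s",
                 "area_um2", "perimeter_um", "circularity", "max_dff",
                 "propagating"),
    rules = list(
      list(name = "t1 > t0", fun = function(d) d$t1_s > d$t0_s),
      list(name = "duration >= 1 s minimum",
           fun = function(d) d$duration_s >= 1 - 1e-9),
      list(name = "area > 0", fun = function(d) d$area_um2 > 0),
      list(name = "circularity in (0, 1 + eps]",
           fun = function(d) d$circularity > 0 & d$circularity <= 1.15),
      list(name = "max_dff finite", fun = function(d) is.finite(d$max_dff)))),
  velocity = list(
    required = c("time_s", "speed_cm_s"),
    rules = list(
      list(name = "speed finite", fun = function(d) is.finite(d$speed_cm_s)),
      list(name = "time sorted",
           fun = function(d) c(TRUE, diff(d$time_s) > 0)))),
  responses = list(
    required = c("cell_id", "niche", "pre_rate", "during_rate", "post_rate",
                 "acute", "persistent"),
    rules = list(
      list(name = "rates >= 0",
           fun = function(d) d$pre_rate >= 0 & d$during_rate >= 0 &
             d$post_rate >= 0),
      list(name = "persistent class consistent with rates",
           fun = function(d) d$persistent ==
             classifyPersistent(d$pre_rate, d$post_rate)))))

#' Validate a pipeline CSV against its declared schema
#'
#' Checks the table's mandatory columns and row-level invariants (e.g. the
#' 1-s minimum event duration) and reports violations by row.
#'
#' @param path CSV path
#' @param schema one of `"events"`, `"velocity"`, `"responses"`
#' @return data.frame of violations (`row`, `rule`); zero rows when valid
#' @export
validateTables <- function(path, schema = c("events", "velocity",
                                            "responses")) {
  schema <- match.arg(schema)
  sc <- .tableSchemas[[schema]]
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (rl in sc$rules) {
    ok <- rl$fun(d)
    if (any(!ok))
      out[[length(out) + 1L]] <- data.frame(row = which(!ok),
                                            rule = rl$name,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row = integer(), rule = character()))
  do.call(rbind, out)
}
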