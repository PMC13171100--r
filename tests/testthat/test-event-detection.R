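test_that("empty and saturated movies are handled explicitly", {
  expect_identical(nEvents(detectEvents(array(0, c(10, 10, 5)))), 0L)
  expect_error(detectEvents(array(5, c(10, 10, 5))), "saturated")
})

test_that("a planted noiseless event is detected with exact geometry", {
  fp <- matrix(FALSE, 40, 40)
  fp[5:34, 10:29] <- TRUE                      # 600 px footprint
  mov <- pulseMovie(fp, f0 = 10, f1 = 14, nT = 40, amp = 1)
  ev <- detectEvents(mov, detectionParams())
  tb <- eventTable(ev)
  expect_identical(nrow(tb), 1L)
  expect_equal(tb$area_um2, 600 * 0.49^2)      # 144.06 um^2
  expect_equal(tb$duration_s, 5 / 1.03)        # frames 10..14 inclusive
  expect_equal(tb$max_dff, 1)
  expect_identical(tb$propagating, "stationary")
})

test_that("the footprint size window rejects small and huge events", {
  small <- matrix(FALSE, 40, 40); small[1:20, 1:20] <- TRUE   # 400 px < 523
  expect_identical(nEvents(detectEvents(pulseMovie(small, 5, 10, 30))), 0L)
  big <- matrix(FALSE, 70, 70); big[3:68, 3:52] <- TRUE       # 3300 px > 3140
  expect_identical(nEvents(detectEvents(pulseMovie(big, 5, 10, 30))), 0L)
})

test_that("sub-second components are discarded by the duration filter", {
  fp <- matrix(FALSE, 40, 40); fp[5:34, 10:29] <- TRUE
  # a single frame at 1.03 Hz lasts 1/1.03 = 0.97 s, below the 1-s minimum
  mov <- pulseMovie(fp, f0 = 10, f1 = 10, nT = 30)
  expect_identical(nEvents(detectEvents(mov)), 0L)
})

test_that("event features match closed forms for disks and rods", {
  # digital disk circularity approaches 1 with radius
  circs <- vapply(c(10, 30, 100), function(r) {
    f <- eventFeatures(diskMask(r), 1, pixelSizeUm = 1)
    f$circularity
  }, numeric(1))
  expect_true(all(circs > 0.9 & circs <= 1.15))
  expect_lt(abs(circs[3] - 1), abs(circs[1] - 1))  # approaches 1 with radius
  expect_true(all(abs(circs - 1) < 0.02))
  f20 <- eventFeatures(diskMask(20), 1, pixelSizeUm = 1)
  expect_gte(f20$circularity, 0.9)
  expect_lte(f20$circularity, 1.05)
  # 1 x 100 rod: closed-form rectangle perimeter 202 * pixel size
  fr <- eventFeatures(rodMask(100), 1, pixelSizeUm = 0.49)
  expect_equal(fr$perimeter_um, 202 * 0.49, tolerance = 0.05)
  expect_lt(fr$circularity, 0.15)
  # single pixel: perimeter 4 * pixel size by convention, flagged
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  fs <- eventFeatures(single, 1, pixelSizeUm = 0.49)
  expect_equal(fs$perimeter_um, 4 * 0.49)
  expect_true(fs$flagged)
  # duration convention: frames 10..14 at 1.03 Hz
  fd <- eventFeatures(diskMask(5), 1, frameRange = c(10, 14), rateHz = 1.03)
  expect_equal(fd$duration_s, (14 - 10 + 1) / 1.03)
  expect_error(eventFeatures(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("propagation classification follows the onset-gradient rule", {
  om <- matrix(NA_real_, 30, 30)
  om[10:20, 5:25] <- 0                          # uniform onsets
  expect_identical(classifyPropagation(om), "stationary")
  om2 <- matrix(NA_real_, 30, 30)
  for (j in 5:25) om2[10:20, j] <- (j - 5) * 0.5  # 10 s lag over ~10 um
  expect_identical(classifyPropagation(om2, pixelSizeUm = 0.49),
                   "propagating")
  # gradient below the distance threshold stays stationary
  om3 <- matrix(NA_real_, 30, 30)
  for (j in 5:25) om3[10:20, j] <- (j - 5) * 0.5
  expect_identical(classifyPropagation(om3, pixelSizeUm = 0.2), "stationary")
})

test_that("planted propagating events are classified from rendered movies", {
  cfg <- simConfig(durationS = 50, fovShape = c(96L, 96L), nCells = 1L,
                   seed = 6)
  truth <- generateGroundTruth(cfg)
  truth$cells$shape <- "round"
  truth$cells$centroid_x_um <- 20; truth$cells$centroid_y_um <- 15
  truth$events <- data.frame(cell_id = "c001", t0_s = 10, t1_s = 20,
                             amplitude = 1, propagating = TRUE,
                             direction_deg = 0)
  rm_ <- renderMovie(cfg, truth)
  arr <- channelData(rm_$movie, "gcamp")
  dff <- sweep(arr, c(1, 2), arr[, , 1],
               FUN = function(a, b) (a - b) / b)
  ev <- detectEvents(dff)
  expect_identical(nEvents(ev), 1L)
  expect_identical(eventTable(ev)$propagating, "propagating")
})

test_that("events map to max-overlap cells and niches use vessel distance", {
  masks <- matrix(0L, 60, 60)
  masks[5:20, 5:20] <- 1L       # touches the vessel band below
  masks[40:55, 40:55] <- 2L     # far from the vessel
  vessel <- matrix(FALSE, 60, 60); vessel[21:24, ] <- TRUE
  fp <- matrix(FALSE, 60, 60); fp[6:18, 6:18] <- TRUE
  tb <- data.frame(event_id = 1L, cell_id = NA_character_, t0_s = 0,
                   t1_s = 5, duration_s = 5, area_um2 = 40,
                   perimeter_um = 25, circularity = 0.8, max_dff = 1,
                   propagating = "stationary", stringsAsFactors = FALSE)
  ev <- calciumEvents(tb, footprints = list(fp), pixelSizeUm = 0.49)
  res <- assignEventsToCells(ev, masks, vessel, perivascularDistanceUm = 5,
                             pixelSizeUm = 0.49)
  expect_identical(eventTable(res$events)$cell_id, "c001")
  expect_identical(res$cells$niche,
                   c("perivascular", "non_perivascular"))
  # event overlapping no cell is kept unassigned
  fpOut <- matrix(FALSE, 60, 60); fpOut[30:35, 1:6] <- TRUE
  ev2 <- calciumEvents(tb, footprints = list(fpOut), pixelSizeUm = 0.49)
  expect_message(res2 <- assignEventsToCells(ev2, masks, vessel),
                 "unassigned")
  expect_identical(eventTable(res2$events)$cell_id, "unassigned")
})

test_that("planted niches are recovered perfectly on rendered fields", {
  cfg <- simConfig(durationS = 10, fovShape = c(160L, 160L), nCells = 6L,
                   seed = 12)
  rm_ <- suppressWarnings(renderMovie(cfg))
  dmap <- EBImage::distmap(matrix(as.numeric(!rm_$vesselMask), 160))
  truthNiche <- vapply(seq_len(cfg@nCells), function(i) {
    px <- which(rm_$cellMasks == i, arr.ind = TRUE)
    if (min(dmap[px]) * 0.49 <= 5) "perivascular" else "non_perivascular"
  }, character(1))
  tb <- data.frame(event_id = 1L, cell_id = NA_character_, t0_s = 0,
                   t1_s = 5, duration_s = 5, area_um2 = 40,
                   perimeter_um = 25, circularity = 0.8, max_dff = 1,
                   propagating = "stationary", stringsAsFactors = FALSE)
  ev <- calciumEvents(tb, footprints = list(rm_$cellMasks == 1L))
  res <- assignEventsToCells(ev, rm_$cellMasks, rm_$vesselMask)
  expect_identical(res$cells$niche, truthNiche)
})

test_that("event tables round-trip through CSV and are validated", {
  cfg <- simConfig(durationS = 600, nCells = 5L, eventRatePerMin = 1,
                   seed = 8)
  ev <- makeEventTable(cfg)
  path <- tempfile(fileext = ".csv")
  writeEventTable(ev, path)
  back <- readEventTable(path)
  expect_equal(eventTable(back), eventTable(ev), tolerance = 1e-12)
  # invalid rows are caught with their id
  tb <- eventTable(ev); tb$t1_s[2] <- tb$t0_s[2] - 1
  write.csv(tb, path, row.names = FALSE)
  expect_error(readEventTable(path), "t1_s must exceed t0_s")
  # missing mandatory column named in the error
  tb2 <- eventTable(ev); tb2$max_dff <- NULL
  write.csv(tb2, path, row.names = FALSE)
  expect_error(readEventTable(path), "max_dff")
  # empty table with header only
  write.csv(eventTable(makeEventTable(
    simConfig(durationS = 10, nCells = 1L, eventRatePerMin = 1e-9,
              seed = 1))), path, row.names = FALSE)
  expect_identical(nEvents(readEventTable(path)), 0L)
  # unknown columns are preserved
  tb3 <- eventTable(ev); tb3$reviewed <- TRUE
  write.csv(tb3, path, row.names = FALSE)
  expect_true("reviewed" %in% names(eventTable(readEventTable(path))))
})

test_that("event rates follow the window definition", {
  t0 <- seq(0, 1799, by = 60)                 # 30 events in 30 min
  expect_equal(eventRate(t0, 0, 1800), 1.0)
  expect_equal(eventRate(numeric(0), 0, 1800), 0.0)
  expect_error(eventRate(t0, 100, 100), "exceed")
  # Poisson rate 0.5/min over 100 cells recovered within 3 SE
  cfg <- simConfig(durationS = 1800, nCells = 100L, eventRatePerMin = 0.5,
                   seed = 13)
  tb <- eventTable(makeEventTable(cfg))
  rates <- vapply(sprintf("c%03d", 1:100), function(cl)
    eventRate(tb$t0_s[tb$cell_id == cl], 0, 1800), numeric(1))
  se <- sqrt(0.5 / 30 / 100)
  expect_lt(abs(mean(rates) - 0.5), 3 * se)
})
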