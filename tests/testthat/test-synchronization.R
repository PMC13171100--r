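test_that("interval arithmetic matches the worked examples", {
  ev <- data.frame(cell_id = c("A", "B"), t0_s = c(10, 15),
                   t1_s = c(20, 25))
  p <- findSyncEvents(ev, 0)
  expect_identical(nrow(p), 1L)
  expect_equal(p$mean_latency_s, -5)       # t0_A - t0_B
  expect_equal(p$first_dur_s, 10)          # first event is A: 20 - 10
  # disjoint intervals with zero tolerance never pair
  ev2 <- data.frame(cell_id = c("A", "B"), t0_s = c(10, 21),
                    t1_s = c(20, 25))
  expect_identical(nrow(findSyncEvents(ev2, 0)), 0L)
  # ...but a 2-s tolerance bridges the 1-s gap
  expect_identical(nrow(findSyncEvents(ev2, 2)), 1L)
  # single cell in the field: empty result
  ev3 <- data.frame(cell_id = "A", t0_s = c(1, 5), t1_s = c(3, 9))
  expect_identical(nrow(findSyncEvents(ev3, 0)), 0L)
})

test_that("sweep join agrees with the brute-force interval oracle", {
  for (seed in 1:12) {
    tb <- randomEventTable(nEvents = 40, nCells = 6, seed = seed)
    tol <- c(0, 0, 1, 5)[seed %% 4 + 1]
    got <- findSyncEvents(tb, tol)
    want <- bruteSyncOracle(tb, tol)
    if (!nrow(want)) {
      expect_identical(nrow(got), 0L)
      next
    }
    wantAgg <- aggregate(latency ~ cellA + cellB, want,
                         function(x) c(n = length(x), m = mean(x)))
    wantAgg <- wantAgg[order(wantAgg$cellA, wantAgg$cellB), ]
    expect_identical(nrow(got), nrow(wantAgg))
    expect_equal(got$n_sync, unname(wantAgg$latency[, "n"]))
    expect_equal(got$mean_latency_s, unname(wantAgg$latency[, "m"]),
                 tolerance = 1e-9)
  }
})

test_that("synchrony is invariant to global time translation", {
  tb <- randomEventTable(30, 5, seed = 42)
  a <- findSyncEvents(tb, 1)
  tb2 <- tb; tb2$t0_s <- tb2$t0_s + 500; tb2$t1_s <- tb2$t1_s + 500
  b <- findSyncEvents(tb2, 1)
  expect_equal(a[, c("cellA", "cellB", "n_sync", "mean_latency_s")],
               b[, c("cellA", "cellB", "n_sync", "mean_latency_s")])
})

test_that("planted shared-trigger synchrony is recovered", {
  set.seed(21)
  nCells <- 40; coactive <- 12           # 30% share a trigger train
  trig <- sort(runif(6, 0, 800))
  rows <- list()
  for (i in seq_len(nCells)) {
    cid <- sprintf("c%03d", i)
    if (i <= coactive) {
      t0 <- trig + runif(length(trig), 0, 0.5)
    } else {
      # isolated cells: one event each, far apart in time
      t0 <- 900 + i * 40
    }
    rows[[i]] <- data.frame(cell_id = cid, t0_s = t0, t1_s = t0 + 5)
  }
  tb <- do.call(rbind, rows)
  p <- findSyncEvents(tb, 0)
  frac <- coactiveFraction(p, sprintf("c%03d", seq_len(nCells)))
  expect_lt(abs(frac - 0.30), 0.05)
})

test_that("pair distances are Euclidean in micrometres", {
  expect_equal(pairDistance(c(0, 0), c(0, 0)), 0)
  expect_equal(pairDistance(c(0, 0), c(30, 40)), 50)
  # all centroids inside the 312 x 212 um field stay under the diagonal
  set.seed(3)
  xs <- runif(50, 0, 312); ys <- runif(50, 0, 212)
  d <- as.numeric(dist(cbind(xs, ys)))
  expect_true(all(d <= sqrt(312^2 + 212^2)))
})

test_that("distance-delay regression matches planted relations", {
  # exact linear: |latency| = 0.01 * distance
  pairs <- data.frame(cellA = "a", cellB = "b",
                      n_sync = 1, mean_latency_s = 0.01 * c(10, 50, 200),
                      first_dur_s = 5, dist_um = c(10, 50, 200))
  r <- distanceDelayRegression(pairs)
  expect_equal(r$slope, 0.01, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(distanceDelayRegression(pairs[1:2, ]), "3 pairs")
  # null: delay independent of distance (expected R^2 small)
  set.seed(8)
  r2s <- replicate(30, {
    p <- data.frame(mean_latency_s = rnorm(80), dist_um = runif(80, 0, 300))
    distanceDelayRegression(p)$r_squared
  })
  expect_lt(mean(r2s), 0.05)
  # zero distance variance flagged
  pz <- data.frame(mean_latency_s = rnorm(5), dist_um = rep(10, 5))
  expect_true(distanceDelayRegression(pz)$flagged)
})

test_that("duration-count regression matches planted relations", {
  pairs <- data.frame(first_dur_s = c(1, 3, 7, 9), n_sync = c(1, 3, 7, 9))
  r <- durationCountRegression(pairs)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(durationCountRegression(pairs[0, ]), "3 pairs")
  set.seed(9)
  r2s <- replicate(30, {
    p <- data.frame(first_dur_s = runif(80, 1, 20),
                    n_sync = rpois(80, 3) + 1)
    durationCountRegression(p)$r_squared
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("interaction typing categorizes partner niche sets", {
  niche <- c(a = "P", b = "P", c = "NP", d = "NP")
  pairs <- data.frame(cellA = c("a", "a", "c"), cellB = c("b", "c", "d"),
                      n_sync = 1, mean_latency_s = 0, first_dur_s = 1,
                      dist_um = 1)
  ty <- interactionTyping(pairs, niche)
  tt <- setNames(ty$perCell$type, ty$perCell$cell_id)
  expect_identical(tt[["b"]], "same_only")     # only partner a is P
  expect_identical(tt[["a"]], "mixed")         # partners b (P) and c (NP)
  expect_identical(tt[["d"]], "same_only")
  expect_equal(sum(ty$proportions), 1)
  # all-to-all synchrony in a mixed field: every cell is mixed
  cells <- names(niche)
  allPairs <- t(combn(cells, 2))
  ap <- data.frame(cellA = allPairs[, 1], cellB = allPairs[, 2],
                   n_sync = 1, mean_latency_s = 0, first_dur_s = 1,
                   dist_um = 1)
  tyAll <- interactionTyping(ap, niche)
  expect_true(all(tyAll$perCell$type == "mixed"))
  expect_error(interactionTyping(pairs, niche[1:2]), "niche label")
})
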