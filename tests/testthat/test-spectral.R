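test_that("trace conditioning picks the SNR-maximizing grid pair", {
  set.seed(4)
  n <- 400
  tr <- sin(2 * pi * 0.02 * (0:(n - 1))) + rnorm(n, 0, 0.1)
  ct <- conditionTrace(tr, orders = 2:5, windows = seq(5, 41, 2))
  # exhaustive re-check: no other grid pair beats the chosen SNR
  dw <- 301; det <- tr - signal::sgolayfilt(tr, 2, min(dw, n - 1 + n %% 2))
  best <- -Inf
  for (w in seq(5, 41, 2)) for (p in 2:5) {
    if (p >= w - 1) next
    sm <- signal::sgolayfilt(det, p, w)
    best <- max(best, var(sm) / var(det - sm))
  }
  expect_equal(ct$snr, best, tolerance = 1e-8)
  expect_false(ct$flagged)
})

test_that("conditioning flags degenerate traces", {
  expect_error(conditionTrace(rnorm(3)), "shorter")
  ctConst <- conditionTrace(rep(2, 100))
  expect_true(ctConst$flagged)
  expect_true(is.na(ctConst$snr))
  # noiseless sinusoid: residual ~ 0, SNR capped and flagged
  ctPure <- conditionTrace(sin(2 * pi * 0.01 * (0:499)))
  expect_true(ctPure$snr >= 1e5)
})

test_that("dominant frequency lands on the planted spectral bin", {
  n <- floor(900 * 1.03)
  t <- (0:(n - 1)) / 1.03
  # 0.01 Hz is exactly bin 9 at resolution 1/900 Hz
  expect_equal(dominantFrequency(sin(2 * pi * 0.01 * t), 1.03), 0.01,
               tolerance = 1e-12)
  # two-tone: the larger-amplitude tone wins
  two <- sin(2 * pi * 0.01 * t) + 0.3 * sin(2 * pi * 0.1 * t)
  expect_equal(dominantFrequency(two, 1.03), 0.01, tolerance = 1e-12)
  # deterministic on identical input
  set.seed(9); w1 <- rnorm(500)
  expect_identical(dominantFrequency(w1, 1.03), dominantFrequency(w1, 1.03))
  expect_warning(res <- dominantFrequency(rep(0, 100)), "all-zero")
  expect_true(is.na(res))
})

test_that("peak counting respects the 10% prominence rule", {
  expect_identical(countPeaks(seq(0, 1, length.out = 50)), 0L)
  # 9 full cycles of a clean sinusoid
  t <- seq(0, 9 - 1e-9, length.out = 2000)
  expect_identical(countPeaks(sin(2 * pi * t)), 9L)
  # 3% ripple maxima are excluded (3% < 10% of range)
  ripple <- sin(2 * pi * t) + 0.03 * sin(2 * pi * 40 * t)
  expect_identical(countPeaks(ripple), 9L)
})

test_that("the elbow rule recovers planted blob counts", {
  set.seed(5)
  one <- matrix(rnorm(300), ncol = 3)
  two <- rbind(matrix(rnorm(150, 0), ncol = 3),
               matrix(rnorm(150, 8), ncol = 3))
  three <- rbind(matrix(rnorm(90, 0), ncol = 3),
                 matrix(rnorm(90, 10), ncol = 3),
                 cbind(rnorm(30, 20), rnorm(30, 0), rnorm(30, 10)))
  expect_identical(chooseKElbow(one, 1:6, seed = 1), 1L)
  expect_identical(chooseKElbow(two, 1:6, seed = 1), 2L)
  expect_identical(chooseKElbow(three, 1:6, seed = 1), 3L)
  expect_identical(chooseKElbow(matrix(1, 10, 2)), 1L)
  expect_error(chooseKElbow(matrix(rnorm(4), 2)), "at least 3")
})

test_that("k-means clustering separates planted feature populations", {
  set.seed(6)
  # population 1: multi-frequency / low SNR; population 2: single slow tone
  n1 <- 40; n2 <- 160
  X <- rbind(
    cbind(runif(n1, 0.05, 0.4), rpois(n1, 25), rnorm(n1, 2, 0.5)),
    cbind(rnorm(n2, 0.01, 0.002), rpois(n2, 9), rnorm(n2, 20, 3)))
  colnames(X) <- c("domfreq_hz", "n_peaks", "snr")
  truthLab <- rep(1:2, c(n1, n2))
  cl <- clusterCells(X, k = 2, seed = 3)
  agree <- max(mean(cl$labels == truthLab), mean(cl$labels == 3 - truthLab))
  expect_gte(agree, 0.95)
  # permutation invariance up to the row mapping
  perm <- sample(nrow(X))
  clP <- clusterCells(X[perm, ], k = 2, seed = 3)
  agreeP <- max(mean(clP$labels == cl$labels[perm]),
                mean(clP$labels == 3 - cl$labels[perm]))
  expect_equal(agreeP, 1)
  # k = 1 collapses everything
  expect_true(all(clusterCells(X, 1)$labels == 1L))
  expect_error(clusterCells(X[1:3, ], 5), "exceed")
  # scaling a feature column has no effect after standardization
  X2 <- X; X2[, 3] <- X2[, 3] * 1000
  expect_identical(clusterCells(X2, 2, seed = 3)$labels, cl$labels)
})

test_that("spectral features pipeline recovers a planted 0.01 Hz tone", {
  set.seed(7)
  n <- floor(900 * 1.03); t <- (0:(n - 1)) / 1.03
  m <- rbind(sin(2 * pi * 0.01 * t) + rnorm(n, 0, 0.1),
             sin(2 * pi * 0.01 * t) + rnorm(n, 0, 0.1))
  rownames(m) <- c("c001", "c002")
  sf <- spectralFeatures(m, rateHz = 1.03)
  expect_equal(sf$domfreq_hz, c(0.01, 0.01), tolerance = 1e-9)
})

test_that("cluster PSD table has one spectrum per cluster", {
  set.seed(10)
  tr <- matrix(rnorm(4 * 600), 4)
  psd <- clusterPSD(tr, c(1, 1, 2, 2), rateHz = 1.03)
  expect_identical(names(psd), c("freq_hz", "cluster_1", "cluster_2"))
  expect_true(all(psd$cluster_1 >= 0))
})

test_that("association test matches closed forms", {
  # balanced independent table: statistic 0, p = 1
  lab <- rep(1:2, each = 20); niche <- rep(c("P", "NP"), 20)
  at <- associationTest(lab, niche)
  expect_equal(at$statistic, 0)
  expect_equal(at$p.value, 1)
  # perfect confounding with 50/50 margins: chi-square = n
  lab2 <- rep(1:2, each = 50)
  niche2 <- rep(c("P", "NP"), each = 50)
  at2 <- associationTest(lab2, niche2)
  expect_equal(at2$statistic, 100)
  expect_error(associationTest(c(1, 1), c("P", "P")), "zero expected|exact")
})

test_that("association p-values are uniform under independence", {
  set.seed(11)
  ps <- replicate(300, {
    lab <- sample(1:2, 240, replace = TRUE)
    niche <- sample(c("P", "NP"), 240, replace = TRUE)
    associationTest(lab, niche)$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})
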