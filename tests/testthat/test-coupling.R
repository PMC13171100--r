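test_that("the lagged design has 125 columns at the analysis rate", {
  n <- 400
  y <- rnorm(n); x <- rnorm(n)
  des <- buildLaggedDesign(y, x, rateHz = 1.03)
  expect_identical(ncol(des$X), 125L)        # +/-62 samples plus lag 0
  expect_equal(range(des$lagsS), c(-62, 62) / 1.03)
  # the zero-lag column is the untrimmed predictor
  expect_equal(unname(des$X[, "lag_+0"]), x[des$keptRows])
  # positive-lag column holds earlier predictor samples
  expect_equal(unname(des$X[, "lag_+3"]), x[des$keptRows - 3])
  expect_error(buildLaggedDesign(rnorm(50), rnorm(50), 1.03), "shorter")
  expect_error(buildLaggedDesign(y, x, 1.03, c(-30, 60)), "symmetric")
})

test_that("a noiseless zero-lag linear response is fit almost perfectly", {
  set.seed(22)
  x <- as.numeric(arima.sim(list(ar = 0.95), 900))
  y <- 2.5 * x
  fit <- fitLaggedGlm(buildLaggedDesign(y, x, 1.03), seed = 1)
  expect_gt(devianceExplained(fit), 0.99)
  expect_equal(fit@lagsS[which.max(abs(fit@coefficients))], 0)
  expect_true(fit@wellFit)
})

test_that("independent response stays below the well-fit threshold", {
  devs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    x <- as.numeric(arima.sim(list(ar = 0.9), 900))
    y <- rnorm(900)
    devianceExplained(fitLaggedGlm(buildLaggedDesign(y, x, 1.03), seed = s))
  }, numeric(1))
  expect_true(all(devs < 0.1))
})

test_that("a planted +10 s coupling lag is localized within 2 samples", {
  v <- makeVelocityTrace(900, 1.03, seed = 23)
  d <- makeCoupledDiameter(v$state, -0.10, 20, 0.01, seed = 24)
  ca <- makeCoupledCaTrace(d / d[1], -2, lagS = 10, noiseSd = 0.05,
                           seed = 25)
  fit <- fitLaggedGlm(buildLaggedDesign(ca, d / d[1], 1.03), seed = 2)
  peakLag <- fit@lagsS[which.max(abs(fit@coefficients))]
  expect_lte(abs(peakLag - 10), 2 / 1.03)
  expect_identical(fit@peakSign, "negative")
})

test_that("vessel and macrophage classification read the planted signs", {
  v <- makeVelocityTrace(900, 1.03, seed = 26)
  dural <- makeCoupledDiameter(v$state, -0.10, 20, 0.01, seed = 27)
  pial <- makeCoupledDiameter(v$state, +0.10, 20, 0.01, seed = 28)
  flat <- makeCoupledDiameter(v$state, 0, 20, 0.01, seed = 29)
  fitD <- fitLaggedGlm(buildLaggedDesign(dural, v$state, 1.03), seed = 3)
  fitP <- fitLaggedGlm(buildLaggedDesign(pial, v$state, 1.03), seed = 3)
  fitF <- fitLaggedGlm(buildLaggedDesign(flat, v$state, 1.03), seed = 3)
  expect_identical(classifyVessel(fitD), "dural")
  expect_identical(classifyVessel(fitP), "pial")
  expect_identical(classifyVessel(fitF), "not_well_fit")
  caNeg <- makeCoupledCaTrace(dural / dural[1], -2, 0, 0.1, seed = 30)
  caPos <- makeCoupledCaTrace(dural / dural[1], +2, 0, 0.1, seed = 31)
  caNull <- makeCoupledCaTrace(dural / dural[1], 0, 0, 0.1, seed = 32)
  fitN <- fitLaggedGlm(buildLaggedDesign(caNeg, dural / dural[1], 1.03),
                       seed = 4)
  fitPo <- fitLaggedGlm(buildLaggedDesign(caPos, dural / dural[1], 1.03),
                        seed = 4)
  fitNu <- fitLaggedGlm(buildLaggedDesign(caNull, dural / dural[1], 1.03),
                        seed = 4)
  expect_identical(classifyMacrophageCoupling(fitN), "negative")
  expect_identical(classifyMacrophageCoupling(fitPo), "positive")
  expect_identical(classifyMacrophageCoupling(fitNu), "not_well_fit")
})

test_that("sign classification is invariant to positive rescaling", {
  v <- makeVelocityTrace(900, 1.03, seed = 33)
  d <- makeCoupledDiameter(v$state, -0.10, 20, 0.01, seed = 34)
  f1 <- fitLaggedGlm(buildLaggedDesign(d, v$state, 1.03), seed = 5)
  f2 <- fitLaggedGlm(buildLaggedDesign(d * 7, v$state * 3, 1.03), seed = 5)
  expect_identical(f1@peakSign, f2@peakSign)
  expect_identical(classifyVessel(f1), classifyVessel(f2))
})

test_that("the contiguous split leaks no information into the test block", {
  v <- makeVelocityTrace(900, 1.03, seed = 35)
  d <- makeCoupledDiameter(v$state, -0.10, 20, 0.01, seed = 36)
  des <- buildLaggedDesign(d, v$state, 1.03)
  fit <- fitLaggedGlm(des, seed = 6)
  expect_gt(devianceExplained(fit), 0.5)
  # shuffling only the held-out block's responses collapses test deviance
  set.seed(37)
  n <- length(des$y); nTrain <- floor(0.75 * n)
  yShuf <- des$y
  yShuf[(nTrain + 1):n] <- sample(yShuf[(nTrain + 1):n])
  desS <- des; desS$y <- yShuf
  fitS <- fitLaggedGlm(desS, seed = 6)
  expect_gt(fitS@devTrain, 0.5)              # training untouched
  expect_lt(devianceExplained(fitS), 0.1)    # held-out signal destroyed
})

test_that("degenerate designs are flagged instead of fit", {
  des <- buildLaggedDesign(rnorm(400), rep(1, 400), 1.03)
  fit <- fitLaggedGlm(des)
  expect_false(fit@wellFit)
  expect_true("degenerate_design" %in% fit@flags)
  expect_error(fitLaggedGlm(buildLaggedDesign(rnorm(140), rnorm(140), 1.03)),
               "test samples")
})

test_that("centre-of-mass delay matches closed forms", {
  lags <- seq(-60, 60, by = 5)
  co <- numeric(length(lags)); co[lags == 5] <- 2
  expect_equal(centerOfMassDelay(co, lags), 5)          # point mass
  sym <- dnorm(lags, 0, 20)
  expect_equal(centerOfMassDelay(sym, lags), 0, tolerance = 1e-12)
  co2 <- numeric(length(lags))
  co2[lags == -10] <- -1; co2[lags == 10] <- 3          # (-10*1+10*3)/4
  expect_equal(centerOfMassDelay(co2, lags), 5)
  expect_warning(res <- centerOfMassDelay(numeric(25), lags), "zero")
  expect_true(is.na(res))
})
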