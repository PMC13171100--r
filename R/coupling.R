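# Two-step lagged Gaussian GLM coupling analysis:
#   (1) vessel diameter ~ locomotion state  -> dural / pial vessel labels
#   (2) macrophage dF/F0 ~ vessel diameter  -> coupling sign and timing
# Elastic-net (alpha = 0.01) with 10-fold cross-validation on a contiguous
# 75% training block; reported deviance explained comes from the held-out
# final 25%.

#' Build a lagged design matrix
#'
#' One predictor column per lag over the +/-60 s window at the analysis
#' rate: column for lag `l` holds the predictor shifted so that row `t`
#' contains `predictor[t - l]` (positive lags = response follows the
#' predictor). Edge rows with undefined lagged values are trimmed.
#'
#' @param response numeric response series
#' @param predictor numeric predictor series, co-sampled with `response`
#' @param rateHz sampling rate, Hz
#' @param lagWindowS symmetric lag window, seconds (default c(-60, 60))
#' @return list with `y`, `X` (rows x lags), `lagsS`, `keptRows`
#' @export
buildLaggedDesign <- function(response, predictor, rateHz = 1.03,
                              lagWindowS = c(-60, 60)) {
  stopifnot(length(response) == length(predictor))
  if (abs(lagWindowS[1L]) != abs(lagWindowS[2L]))
    stop("lag window must be symmetric about 0")
  assertFinite(response, "response"); assertFinite(predictor, "predictor")
  L <- round(lagWindowS[2L] * rateHz)
  n <- length(response)
  if (n <= 2L * L + 1L)
    stop("series shorter than the lag window span")
  lags <- seq(-L, L)
  rows <- (L + 1L):(n - L)
  X <- vapply(lags, function(l) predictor[rows - l],
              numeric(length(rows)))
  colnames(X) <- sprintf("lag_%+d", lags)
  list(y = response[rows], X = X, lagsS = lags / rateHz, keptRows = rows)
}

#' Fit the lagged elastic-net Gaussian GLM
#'
#' The first `trainFrac` of rows (temporally contiguous) trains the model;
#' the penalty is chosen by `folds`-fold cross-validation with contiguous
#' temporal fold blocks, coefficients are refit at the chosen penalty, and
#' deviance explained `1 - SSE/SST` is computed on the held-out final block
#' (null model = training-set mean). Columns are z-scored with train-set
#' statistics. Fits with held-out deviance explained of at least 0.1 are
#' flagged well-fit.
#'
#' @param design output of [buildLaggedDesign()]
#' @param alpha elastic-net mixing (default 0.01, i.e. almost ridge)
#' @param folds cross-validation folds (contiguous blocks)
#' @param trainFrac fraction of rows in the training block
#' @param seed RNG seed (fold assignment is deterministic; the seed guards
#'   glmnet internals)
#' @param nlambda length of the penalty grid
#' @return a [LaggedGLMFit-class]
#' @export
fitLaggedGlm <- function(design, alpha = 0.01, folds = 10L,
                         trainFrac = 0.75, seed = 1L, nlambda = 100L) {
  y <- design$y; X <- design$X; lags <- design$lagsS
  n <- length(y)
  nTrain <- floor(trainFrac * n)
  nTest <- n - nTrain
  if (nTest < 10L) stop("fewer than 10 test samples")
  trainIdx <- seq_len(nTrain); testIdx <- (nTrain + 1L):n
  mu <- colMeans(X[trainIdx, , drop = FALSE])
  sdv <- apply(X[trainIdx, , drop = FALSE], 2L, sd)
  degenerate <- all(sdv == 0)
  if (degenerate)
    return(new("LaggedGLMFit", coefficients = rep(0, length(lags)),
               lagsS = lags, alpha = alpha, lambda = NA_real_,
               devTrain = NA_real_, devTest = NA_real_, wellFit = FALSE,
               peakSign = "zero", comDelayS = NA_real_,
               flags = "degenerate_design",
               standardization = list(mean = mu, sd = sdv)))
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  foldid <- as.integer(cut(seq_len(nTrain), breaks = folds, labels = FALSE))
  cvfit <- withSeed(seed,
    glmnet::cv.glmnet(Z[trainIdx, , drop = FALSE], y[trainIdx],
                      family = "gaussian", alpha = alpha, foldid = foldid,
                      nlambda = nlambda, standardize = FALSE))
  co <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
  devOf <- function(idx) {
    pr <- as.numeric(predict(cvfit, Z[idx, , drop = FALSE],
                             s = "lambda.min"))
    1 - sum((y[idx] - pr)^2) / sum((y[idx] - mean(y[trainIdx]))^2)
  }
  devTest <- devOf(testIdx)
  flags <- character(0)
  peak <- which.max(abs(co))
  peakSign <- if (all(co == 0)) {
    flags <- c(flags, "all_zero_coefficients")
    "zero"
  } else if (co[peak] < 0) "negative" else "positive"
  com <- if (all(co == 0)) NA_real_ else centerOfMassDelay(co, lags)
  new("LaggedGLMFit", coefficients = co, lagsS = lags, alpha = alpha,
      lambda = cvfit$lambda.min, devTrain = devOf(trainIdx),
      devTest = devTest, wellFit = devTest >= 0.1, peakSign = peakSign,
      comDelayS = com, flags = flags,
      standardization = list(mean = mu, sd = sdv,
                             null = "train-mean null deviance"))
}

#' Centre-of-mass delay of a lagged coefficient vector
#'
#' `sum(lag * |coef|) / sum(|coef|)`: the |coefficient|-weighted mean lag,
#' summarizing when the response follows the predictor.
#'
#' @param coefficients per-lag coefficients
#' @param lagsS lag grid, seconds
#' @return delay in seconds (`NA` with a warning if all coefficients are 0)
#' @export
centerOfMassDelay <- function(coefficients, lagsS) {
  stopifnot(length(coefficients) == length(lagsS))
  w <- abs(coefficients)
  if (sum(w) == 0) {
    warning("all coefficients are zero: centre-of-mass delay undefined")
    return(NA_real_)
  }
  sum(lagsS * w) / sum(w)
}

#' Classify a vessel from its locomotion-GLM fit
#'
#' Vessels whose diameter ~ locomotion fit falls below the 0.1 held-out
#' deviance threshold are `"not_well_fit"`. Well-fit vessels are `"dural"`
#' when the coefficient at the largest |coefficient| lag is negative
#' (locomotion-coupled constriction) and `"pial"` when positive (dilation).
#'
#' @param fit a [LaggedGLMFit-class] from the diameter ~ locomotion model
#' @return `"dural"`, `"pial"`, `"not_well_fit"`, or `"unclassified"`
#' @export
classifyVessel <- function(fit) {
  stopifnot(is(fit, "LaggedGLMFit"))
  if (!isTRUE(fit@wellFit)) return("not_well_fit")
  switch(fit@peakSign, negative = "dural", positive = "pial",
         { warning("zero peak coefficient: vessel unclassified")
           "unclassified" })
}

#' Classify macrophage-to-vasomotion coupling from its diameter-GLM fit
#'
#' As [classifyVessel()] but for the Ca2+ ~ diameter model: well-fit cells
#' are labelled by the sign of the peak coefficient (`"negative"` = Ca2+
#' rises with vasoconstriction, `"positive"` = Ca2+ rises with dilation).
#'
#' @param fit a [LaggedGLMFit-class] from the Ca2+ ~ diameter model
#' @return `"negative"`, `"positive"`, `"not_well_fit"`, or `"unclassified"`
#' @export
classifyMacrophageCoupling <- function(fit) {
  stopifnot(is(fit, "LaggedGLMFit"))
  if (!isTRUE(fit@wellFit)) return("not_well_fit")
  switch(fit@peakSign, negative = "negative", positive = "positive",
         { warning("zero peak coefficient: coupling unclassified")
           "unclassified" })
}
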