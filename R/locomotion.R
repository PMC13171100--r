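# Two-state (rest/run) Gaussian hidden Markov model for wheel velocity.
# EM (scaled forward-backward) and Viterbi are implemented here: the model
# is small (2 states, Gaussian emissions) and fully specified.

.hmmForwardBackward <- function(x, means, sds, A, p0) {
  n <- length(x)
  B <- cbind(stats::dnorm(x, means[1L], sds[1L]),
             stats::dnorm(x, means[2L], sds[2L]))
  B <- pmax(B, 1e-300)
  alpha <- matrix(0, n, 2L); beta <- matrix(0, n, 2L)
  cvec <- numeric(n)
  alpha[1L, ] <- p0 * B[1L, ]
  cvec[1L] <- sum(alpha[1L, ]); alpha[1L, ] <- alpha[1L, ] / cvec[1L]
  for (t in 2:n) {
    alpha[t, ] <- (alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(alpha[t, ]); alpha[t, ] <- alpha[t, ] / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1L):1L)
    beta[t, ] <- (A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # expected transition counts
  xi <- matrix(0, 2L, 2L)
  for (i in 1:2) for (j in 1:2)
    xi[i, j] <- sum(alpha[-n, i] * A[i, j] * B[-1L, j] * beta[-1L, j] /
                      cvec[-1L])
  list(gamma = gamma, xi = xi, logLik = sum(log(cvec)))
}

.hmmEM <- function(x, means, sds, A, p0, maxIter = 100L, tol = 1e-6) {
  ll0 <- -Inf
  sdFloor <- max(sd(x) * 1e-3, 1e-8)
  for (it in seq_len(maxIter)) {
    fb <- .hmmForwardBackward(x, means, sds, A, p0)
    g <- fb$gamma
    means <- colSums(g * x) / colSums(g)
    sds <- pmax(sqrt(colSums(g * (outer(x, means, "-")^2)) / colSums(g)),
                sdFloor)
    A <- fb$xi / rowSums(fb$xi)
    p0 <- g[1L, ]
    if (abs(fb$logLik - ll0) < tol) break
    ll0 <- fb$logLik
  }
  list(means = means, sds = sds, A = A, p0 = p0, logLik = fb$logLik)
}

#' Train a two-state locomotion HMM on concatenated velocity traces
#'
#' All velocity traces of one mouse are concatenated (in the order given,
#' which is recorded) and a 2-state Gaussian-emission hidden Markov model is
#' fitted by expectation-maximization with k-means initialization and
#' `nRestarts` jittered restarts under a fixed seed. States are relabelled
#' so that "run" (state 2) has the larger emission mean.
#'
#' @param traces numeric vector or list of numeric speed vectors (cm/s)
#' @param rateHz sampling rate, Hz
#' @param nRestarts EM restarts with jittered initial means
#' @param seed RNG seed
#' @param maxIter,tol EM stopping rule
#' @return a [LocomotionModel-class]
#' @export
trainLocomotionHmm <- function(traces, rateHz = 1.03, nRestarts = 5L,
                               seed = 1L, maxIter = 100L, tol = 1e-6) {
  x <- if (is.list(traces)) unlist(traces, use.names = FALSE) else traces
  if (length(x) < 2L) stop("need at least 2 samples")
  assertFinite(x, "traces")
  if (sd(x) == 0)
    stop("velocity has zero variance (single-state data); ",
         "use a simple speed threshold instead")
  best <- NULL
  withSeed(seed, {
    km <- kmeans(x, centers = 2L, nstart = 5L)
    mu0 <- sort(km$centers[, 1L])
    s0 <- rep(max(sd(x) / 4, 1e-3), 2L)
    for (r in seq_len(nRestarts)) {
      mu <- if (r == 1L) mu0 else sort(mu0 + rnorm(2L, 0, diff(mu0) / 10))
      fit <- tryCatch(
        .hmmEM(x, mu, s0, matrix(c(0.95, 0.05, 0.05, 0.95), 2L,
                                 byrow = TRUE),
               c(0.5, 0.5), maxIter, tol),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik))
        best <- fit
    }
  })
  if (is.null(best)) stop("EM failed on all restarts")
  ord <- order(best$means)            # rest first, run second
  new("LocomotionModel", means = best$means[ord], sds = best$sds[ord],
      transMat = best$A[ord, ord, drop = FALSE], initProb = best$p0[ord],
      rateHz = rateHz, logLik = best$logLik)
}

#' Decode locomotion states with the Viterbi path
#'
#' Most-likely state sequence of a velocity trace under a trained
#' [LocomotionModel-class]; bouts are extracted with the default 2-s rule.
#'
#' @param speed numeric velocity trace (cm/s)
#' @param model a [LocomotionModel-class] trained on the same mouse
#' @param rateHz sampling rate of `speed`; must match the model
#' @return a [LocomotionStates-class]
#' @export
decodeStates <- function(speed, model, rateHz = model@rateHz) {
  stopifnot(is(model, "LocomotionModel"))
  if (abs(rateHz - model@rateHz) > 1e-9)
    stop("sampling rate ", rateHz, " Hz does not match the model (",
         model@rateHz, " Hz)")
  n <- length(speed)
  if (!n)
    return(new("LocomotionStates", states = integer(0), rateHz = rateHz,
               bouts = .emptyBouts()))
  logB <- cbind(stats::dnorm(speed, model@means[1L], model@sds[1L],
                             log = TRUE),
                stats::dnorm(speed, model@means[2L], model@sds[2L],
                             log = TRUE))
  logA <- log(pmax(model@transMat, 1e-300))
  v <- matrix(-Inf, n, 2L); ptr <- matrix(1L, n, 2L)
  v[1L, ] <- log(pmax(model@initProb, 1e-300)) + logB[1L, ]
  for (t in 2:n) for (j in 1:2) {
    cand <- v[t - 1L, ] + logA[, j]
    ptr[t, j] <- which.max(cand)
    v[t, j] <- cand[ptr[t, j]] + logB[t, j]
  }
  states <- integer(n)
  states[n] <- which.max(v[n, ])
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- ptr[t + 1L, states[t + 1L]]
  states <- states - 1L                 # 0 = rest, 1 = run
  new("LocomotionStates", states = states, rateHz = rateHz,
      bouts = extractBouts(states, rateHz))
}

.emptyBouts <- function() {
  data.frame(start_s = numeric(), end_s = numeric(), duration_s = numeric())
}

#' Extract locomotion bouts from a state sequence
#'
#' Maximal runs of the run state lasting at least `minDurationS` (a run of
#' `n` samples at rate `r` lasts `n / r` seconds; the threshold is
#' inclusive). Bout edges snap to analysis-rate samples.
#'
#' @param states 0/1 state vector or a [LocomotionStates-class]
#' @param rateHz sampling rate, Hz
#' @param minDurationS minimum sustained duration, seconds (default 2)
#' @return data.frame of bouts: start_s, end_s, duration_s
#' @export
extractBouts <- function(states, rateHz = 1.03, minDurationS = 2) {
  if (is(states, "LocomotionStates")) {
    rateHz <- states@rateHz
    states <- states@states
  }
  if (!length(states)) return(.emptyBouts())
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths / rateHz >= minDurationS - 1e-9
  if (!any(keep)) return(.emptyBouts())
  data.frame(start_s = (starts[keep] - 1L) / rateHz,
             end_s = ends[keep] / rateHz,
             duration_s = r$lengths[keep] / rateHz)
}
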