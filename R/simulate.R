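## Seeded synthetic stand-ins for the subject, the eye tracker and the
## scanner: a two-state (centre-fixation / elsewhere) semi-Markov gaze
## process with a compliance parameter, and BOLD time series generated as
## design x beta + AR(1) noise.

#' Synthetic gaze model
#'
#' A two-state semi-Markov subject: in the compliant state gaze rests at
#' the screen centre with Gaussian jitter, in the non-compliant state it
#' rests at a random eccentric point. Dwell times are exponential with
#' means `compliance * meanCycle` and `(1 - compliance) * meanCycle`, so
#' the long-run probability of centre fixation at any scheduled check
#' equals `compliance` by construction. Samples drop out (are flagged
#' invalid) independently with probability `dropoutRate`.
#'
#' @param compliance probability in `[0, 1]` of centre fixation at any
#'   point in time.
#' @param fixationNoiseSd gaze jitter SD (degrees); small enough by
#'   default that a 200-ms window keeps dispersion within 1 degree.
#' @param offCenterRange eccentricity range (degrees) of non-compliant
#'   resting points.
#' @param meanCycle mean duration (ms) of one compliant + non-compliant
#'   cycle.
#' @param dropoutRate per-sample probability of tracking loss.
#' @param sampleRate sampling rate (Hz), default 60.
#' @return list of class `gazeModel`.
#' @export
gazeModel <- function(compliance = 0.5, fixationNoiseSd = 0.05,
                      offCenterRange = c(3, 8), meanCycle = 4000,
                      dropoutRate = 0, sampleRate = 60) {
    stopifnot(compliance >= 0, compliance <= 1,
              dropoutRate >= 0, dropoutRate <= 1, sampleRate > 0,
              fixationNoiseSd >= 0, meanCycle > 0)
    structure(list(compliance = compliance,
                   fixationNoiseSd = fixationNoiseSd,
                   offCenterRange = offCenterRange, meanCycle = meanCycle,
                   dropoutRate = dropoutRate, sampleRate = sampleRate),
              class = "gazeModel")
}

#' Simulate a gaze stream
#'
#' Draws a piecewise-stationary fixation trajectory from a [gazeModel()]:
#' alternating compliant (centre) and non-compliant (eccentric) epochs
#' with exponential dwell times, Gaussian jitter around the epoch's
#' resting point, and independent dropout. Fully seeded: identical seeds
#' give identical streams.
#'
#' @param model a [gazeModel()].
#' @param duration stream length (ms).
#' @param seed optional RNG seed.
#' @return gaze stream data.frame (`t`, `x`, `y`, `valid`).
#' @examples
#' g <- simulateGaze(gazeModel(compliance = 1), duration = 2000, seed = 1)
#' isFixated(g, fixationParams(), 1000)
#' @export
simulateGaze <- function(model, duration, seed = NULL) {
    stopifnot(duration > 0)
    if (!is.null(seed)) set.seed(seed)
    t <- seq(0, duration, by = 1000 / model$sampleRate)
    n <- length(t)

    c0 <- model$compliance
    meanIn <- c0 * model$meanCycle
    meanOut <- (1 - c0) * model$meanCycle
    ## epoch boundaries covering [0, duration]
    state <- logical(0)    # TRUE = compliant
    bounds <- numeric(0)
    cur <- if (c0 >= 1) TRUE else if (c0 <= 0) FALSE
           else runif(1) < c0
    at <- 0
    while (at <= duration) {
        dwell <- if (cur) {
            if (c0 >= 1) duration + 1 else rexp(1, 1 / meanIn)
        } else {
            if (c0 <= 0) duration + 1 else rexp(1, 1 / meanOut)
        }
        state <- c(state, cur)
        bounds <- c(bounds, at + dwell)
        at <- at + dwell
        cur <- !cur
    }

    epoch <- findInterval(t, bounds, left.open = TRUE) + 1L
    compliant <- state[epoch]
    nEpoch <- length(state)
    angle <- runif(nEpoch, 0, 2 * pi)
    radius <- runif(nEpoch, model$offCenterRange[1],
                    model$offCenterRange[2])
    cx <- ifelse(state, 0, radius * cos(angle))
    cy <- ifelse(state, 0, radius * sin(angle))

    x <- cx[epoch] + rnorm(n, 0, model$fixationNoiseSd)
    y <- cy[epoch] + rnorm(n, 0, model$fixationNoiseSd)
    valid <- if (model$dropoutRate > 0) runif(n) >= model$dropoutRate
             else rep(TRUE, n)
    data.frame(t = t, x = x, y = y, valid = valid)
}

#' Synthetic BOLD model
#'
#' Ground truth for voxel time series: per-regressor, per-voxel effect
#' sizes plus a baseline and AR(1) noise.
#'
#' @param trueBeta numeric matrix, design parameters x voxels (a vector
#'   is one voxel).
#' @param noiseSd innovation standard deviation of the noise.
#' @param ar1 lag-1 autocorrelation of the noise, `|ar1| < 1`.
#' @param baseline constant signal level.
#' @return list of class `boldModel`.
#' @export
boldModel <- function(trueBeta, noiseSd = 1, ar1 = 0, baseline = 100) {
    trueBeta <- as.matrix(trueBeta)
    stopifnot(abs(ar1) < 1, noiseSd >= 0)
    structure(list(trueBeta = trueBeta, noiseSd = noiseSd, ar1 = ar1,
                   baseline = baseline), class = "boldModel")
}

#' Simulate voxel time series from a design
#'
#' Generates `Y = baseline + X beta + e` on the rows of the (trimmed)
#' design, with `e` an AR(1) process with the model's lag-1 parameter and
#' innovation SD. Seeded and reproducible.
#'
#' @param design a [DesignMatrix-class].
#' @param model a [boldModel()]; its `trueBeta` must have one row per
#'   design column.
#' @param seed optional RNG seed.
#' @return numeric matrix, scans x voxels.
#' @export
simulateBold <- function(design, model, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    X <- design@values
    beta <- model$trueBeta
    if (nrow(beta) != ncol(X))
        stop(sprintf("trueBeta has %d rows but the design has %d columns",
                     nrow(beta), ncol(X)), call. = FALSE)
    n <- nrow(X)
    v <- ncol(beta)
    innov <- matrix(rnorm(n * v, 0, model$noiseSd), n, v)
    eps <- if (model$ar1 != 0)
        apply(innov, 2L, function(z)
            as.numeric(stats::filter(z, model$ar1, method = "recursive")))
    else innov
    model$baseline + X %*% beta + eps
}
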