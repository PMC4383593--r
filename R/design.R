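## Dynamic design construction: presented trials are mapped through their
## transfer functions onto regressor events, laid out on a fine microtime
## grid, convolved with the haemodynamic kernel, and downsampled to scan
## times. Events remain the source of truth; the sampled columns are
## recomputable from them at any time.

#' Map a presented trial onto a regressor event
#'
#' A transfer function turns a log entry into a design-matrix event:
#' onset = actual onset + `timeOffset`; duration = presentation duration
#' times `durationScale` (a factor of 0 yields an impulse, i.e. event
#' modelling); weight = `parametricScale`.
#'
#' @param entry a single row of [entries()] (needs `actualOnset`,
#'   `duration`), or any list with those fields.
#' @param tf a single row of [transferFunctions()].
#' @return data.frame with columns `onset`, `duration`, `weight` (ms, ms,
#'   dimensionless).
#' @export
applyTransferFunction <- function(entry, tf) {
    data.frame(onset = entry$actualOnset + tf$timeOffset,
               duration = entry$duration * tf$durationScale,
               weight = tf$parametricScale)
}

#' Sample a dynamic regressor on the scan grid
#'
#' Builds a stick/boxcar indicator of the events on a microtime grid,
#' convolves it with the haemodynamic kernel, and downsamples at scan
#' times `0, tr, 2*tr, ...`. Derivative columns convolve the same
#' indicator with first/second finite differences of the kernel.
#'
#' @param events data.frame of regressor events (`onset`, `duration` in
#'   ms, `weight`); zero rows give zero columns.
#' @param tr repetition time (ms).
#' @param nScans number of scans to sample.
#' @param microtime microtime resolution (ms); the default 100 ms keeps
#'   8-ms onset shifts visible after accumulation while staying cheap.
#' @param firstDerivative,secondDerivative add temporal-derivative
#'   columns.
#' @param zeroMean mean-centre each sampled column.
#' @param maxLength modelled run length (ms); an event ending beyond it
#'   is a validation error. `NULL` disables the check.
#' @param hrf an [hrfParams()].
#' @return numeric matrix, `nScans` rows, one column per kernel
#'   (response, then requested derivatives).
#' @export
sampleRegressor <- function(events, tr, nScans, microtime = 100,
                            firstDerivative = FALSE,
                            secondDerivative = FALSE, zeroMean = FALSE,
                            maxLength = NULL, hrf = hrfParams()) {
    nScans <- as.integer(nScans)
    if (!is.null(maxLength) && nrow(events)) {
        over <- events$onset + events$duration > maxLength
        if (any(over))
            stop(sprintf("event at %g ms extends beyond the modelled run length (%g ms)",
                         events$onset[which(over)[1L]], maxLength),
                 call. = FALSE)
    }
    runLen <- (nScans - 1L) * tr
    nGrid <- floor(runLen / microtime) + 1L
    u <- numeric(nGrid)
    for (k in seq_len(nrow(events))) {
        on <- events$onset[k]; du <- events$duration[k]
        w <- events$weight[k]
        if (on > runLen) next
        if (du <= 0) {
            b <- floor(on / microtime) + 1L
            u[b] <- u[b] + w
        } else {
            b0 <- floor(on / microtime) + 1L
            b1 <- min(nGrid, ceiling((on + du) / microtime))
            u[b0:b1] <- u[b0:b1] + w
        }
    }

    dtSec <- microtime / 1000
    kernT <- seq(0, 32, by = dtSec)
    h <- gloverHrf(kernT, hrf)
    kernels <- list(h)
    if (firstDerivative || secondDerivative) {
        d1 <- c(diff(h), 0) / dtSec
        if (firstDerivative) kernels <- c(kernels, list(d1))
        if (secondDerivative)
            kernels <- c(kernels, list(c(diff(d1), 0) / dtSec))
    }

    scanIdx <- floor((seq_len(nScans) - 1L) * tr / microtime) + 1L
    out <- vapply(kernels, function(k) {
        conv <- convolve(u, rev(k), type = "open")[seq_len(nGrid)]
        col <- conv[scanIdx]
        if (zeroMean) col <- col - mean(col)
        col
    }, numeric(nScans))
    out
}

#' Build the design matrix from an adapted run
#'
#' Collects every presented, non-filler trial whose media object carries a
#' regressor assignment, maps it through its transfer function
#' ([applyTransferFunction()]), samples each declared dynamic regressor
#' (plus requested derivative columns) on the scan grid, appends optional
#' nuisance covariates and an intercept, and discards the first
#' `ignoreScansAtStart` scans.
#'
#' @param log an [EventLog-class] from [runClosedLoop()].
#' @param spec the [ExperimentSpec-class] of the run.
#' @param nScans total scans; default covers [runEnd()] at the
#'   specification's TR.
#' @param nuisance optional numeric matrix of nuisance covariates (e.g.
#'   motion parameters) with either `nScans` rows or already-trimmed
#'   rows; estimating such covariates is out of scope here.
#' @param microtime,hrf see [sampleRegressor()].
#' @return A [DesignMatrix-class].
#' @export
buildDesignMatrix <- function(log, spec, nScans = NULL, nuisance = NULL,
                              microtime = 100, hrf = hrfParams()) {
    tr <- spec@tr
    if (is.null(nScans))
        nScans <- max(ceiling(log@runEnd / tr) + 1,
                      spec@ignoreScansAtStart + 10)
    nScans <- as.integer(nScans)
    if (nScans <= spec@ignoreScansAtStart)
        stop("nScans must exceed ignoreScansAtStart", call. = FALSE)

    e <- log@entries
    e <- e[!e$inserted & !e$abandoned, , drop = FALSE]
    m <- spec@media
    tfs <- spec@transferFunctions
    mi <- match(e$mediaRef, m$id)
    regOf <- m$regressorRef[mi]
    tfOf <- m$transferFunctionRef[mi]

    rg <- spec@regressorSpecs
    cols <- list()
    for (r in seq_len(nrow(rg))) {
        sel <- which(!is.na(regOf) & regOf == rg$id[r])
        events <- if (length(sel)) {
            do.call(rbind, lapply(sel, function(k) {
                tfRow <- tfs[match(tfOf[k], tfs$id), , drop = FALSE]
                applyTransferFunction(e[k, , drop = FALSE], tfRow)
            }))
        } else {
            data.frame(onset = numeric(), duration = numeric(),
                       weight = numeric())
        }
        sm <- sampleRegressor(events, tr, nScans, microtime = microtime,
                              firstDerivative = rg$firstDerivative[r],
                              secondDerivative = rg$secondDerivative[r],
                              zeroMean = rg$zeroMean[r],
                              maxLength = rg$maxLength[r], hrf = hrf)
        nm <- rg$id[r]
        colnames(sm) <- c(nm, paste0(nm, "_d1"), paste0(nm, "_d2")
                          )[seq_len(ncol(sm))]
        cols[[length(cols) + 1L]] <- sm
    }
    X <- if (length(cols)) do.call(cbind, cols)
         else matrix(numeric(), nScans, 0)

    if (!is.null(nuisance)) {
        nuisance <- as.matrix(nuisance)
        if (is.null(colnames(nuisance)))
            colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    }

    drop <- spec@ignoreScansAtStart
    keep <- seq.int(drop + 1L, nScans)
    X <- X[keep, , drop = FALSE]
    if (!is.null(nuisance)) {
        if (nrow(nuisance) == nScans)
            nuisance <- nuisance[keep, , drop = FALSE]
        else if (nrow(nuisance) != length(keep))
            stop("nuisance covariates must have nScans or trimmed rows",
                 call. = FALSE)
        X <- cbind(X, nuisance)
    }
    X <- cbind(X, intercept = rep(1, length(keep)))
    new("DesignMatrix", values = X, tr = tr, nScans = nScans,
        ignoreScansAtStart = drop)
}
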