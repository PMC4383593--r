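## Central containers. Structural validity lives here; cross-reference
## integrity is the job of validateRules(), so that deliberately broken
## specifications can still be constructed and inspected.

.emptyMedia <- function() {
    data.frame(id = character(), name = character(), kind = character(),
               contentRef = character(), posX = numeric(), posY = numeric(),
               constraintRef = character(), regressorRef = character(),
               transferFunctionRef = character(),
               stringsAsFactors = FALSE)
}

.emptyTimetable <- function() {
    data.frame(onset = numeric(), duration = numeric(),
               mediaRef = character(), stringsAsFactors = FALSE)
}

.emptySystemVariables <- function() {
    data.frame(source = character(), id = character(), name = character(),
               stringsAsFactors = FALSE)
}

.emptyTransferFunctions <- function() {
    data.frame(id = character(), timeOffset = numeric(),
               durationScale = numeric(), parametricScale = numeric(),
               stringsAsFactors = FALSE)
}

.emptyRegressorSpecs <- function() {
    data.frame(id = character(), name = character(), maxLength = numeric(),
               refFct = character(), firstDerivative = logical(),
               secondDerivative = logical(), zeroMean = logical(),
               stringsAsFactors = FALSE)
}

.checkColumns <- function(df, expected, what) {
    miss <- setdiff(names(expected), colnames(df))
    if (length(miss))
        return(sprintf("%s is missing column(s): %s", what,
                       paste(miss, collapse = ", ")))
    NULL
}

#' ExperimentSpec: a parsed adaptive experiment description
#'
#' Container for a fully parsed experiment: stimuli (media objects), the
#' presentation timetable, and the adaptive constructs — system variables,
#' constraints with stimulus actions, transfer functions, and dynamic
#' time-based regressor declarations. All times are integer milliseconds
#' from run start.
#'
#' @slot media data.frame of media objects (id, name, kind, contentRef,
#'   posX, posY, constraintRef, regressorRef, transferFunctionRef).
#' @slot timetable data.frame of stimulus events (onset, duration,
#'   mediaRef), sorted by onset.
#' @slot systemVariables data.frame (source, id, name); a source is a
#'   reverse-DNS plugin identifier.
#' @slot constraints named list; each element has fields id, conditions
#'   (character vector of system-variable ids, combined as a conjunction),
#'   actionsThen and actionsElse (lists of stimulus actions).
#' @slot transferFunctions data.frame (id, timeOffset, durationScale,
#'   parametricScale).
#' @slot regressorSpecs data.frame (id, name, maxLength, refFct,
#'   firstDerivative, secondDerivative, zeroMean).
#' @slot ignoreScansAtStart integer, leading scans discarded before GLM.
#' @slot tr numeric, scanner repetition time in milliseconds.
#'
#' @seealso [parseExperiment()], [validateRules()], [writeExperiment()]
#' @exportClass ExperimentSpec
setClass("ExperimentSpec",
    representation(media = "data.frame",
                   timetable = "data.frame",
                   systemVariables = "data.frame",
                   constraints = "list",
                   transferFunctions = "data.frame",
                   regressorSpecs = "data.frame",
                   ignoreScansAtStart = "integer",
                   tr = "numeric"),
    prototype(media = .emptyMedia(),
              timetable = .emptyTimetable(),
              systemVariables = .emptySystemVariables(),
              constraints = list(),
              transferFunctions = .emptyTransferFunctions(),
              regressorSpecs = .emptyRegressorSpecs(),
              ignoreScansAtStart = 0L,
              tr = 2000))

setValidity("ExperimentSpec", function(object) {
    msgs <- c(
        .checkColumns(object@media, .emptyMedia(), "media"),
        .checkColumns(object@timetable, .emptyTimetable(), "timetable"),
        .checkColumns(object@systemVariables, .emptySystemVariables(),
                      "systemVariables"),
        .checkColumns(object@transferFunctions, .emptyTransferFunctions(),
                      "transferFunctions"),
        .checkColumns(object@regressorSpecs, .emptyRegressorSpecs(),
                      "regressorSpecs"))
    if (length(object@tr) != 1L || object@tr <= 0)
        msgs <- c(msgs, "tr must be a single positive number (ms)")
    if (length(object@ignoreScansAtStart) != 1L ||
        object@ignoreScansAtStart < 0L)
        msgs <- c(msgs, "ignoreScansAtStart must be a single non-negative integer")
    if (is.unsorted(object@timetable$onset))
        msgs <- c(msgs, "timetable must be sorted by onset")
    if (length(msgs)) msgs else TRUE
})

.logColumns <- c(mediaRef = "character", plannedOnset = "numeric",
                 actualOnset = "numeric", duration = "numeric",
                 delay = "numeric", adapted = "logical",
                 validAtOnset = "logical", nInsertions = "integer",
                 inserted = "logical", abandoned = "logical")

.emptyLogEntries <- function() {
    out <- data.frame(mediaRef = character(), plannedOnset = numeric(),
                      actualOnset = numeric(), duration = numeric(),
                      delay = numeric(), adapted = logical(),
                      validAtOnset = logical(), nInsertions = integer(),
                      inserted = logical(), abandoned = logical(),
                      stringsAsFactors = FALSE)
    out
}

#' EventLog: planned vs. actual presentation timing of a run
#'
#' One row per presented event (including inserted filler events), with the
#' planned onset from the original timetable, the actual onset after
#' closed-loop adaptation, the accumulated delay, the number of filler
#' insertions spent waiting, and whether the gating constraint held at
#' presentation.
#'
#' @slot entries data.frame with columns mediaRef, plannedOnset,
#'   actualOnset, duration, delay, adapted, validAtOnset, nInsertions,
#'   inserted, abandoned. Times in milliseconds.
#' @slot runEnd numeric; offset (ms) of the last presented event.
#'
#' @seealso [runClosedLoop()], [writeEventLog()]
#' @exportClass EventLog
setClass("EventLog",
    representation(entries = "data.frame", runEnd = "numeric"),
    prototype(entries = .emptyLogEntries(), runEnd = 0))

setValidity("EventLog", function(object) {
    msgs <- .checkColumns(object@entries, .emptyLogEntries(), "entries")
    e <- object@entries
    if (is.null(msgs) && nrow(e)) {
        if (any(e$delay < 0, na.rm = TRUE))
            msgs <- c(msgs, "delays must be non-negative")
        bad <- !e$adapted & !e$inserted &
            (e$delay != 0 | e$nInsertions != 0L)
        if (any(bad, na.rm = TRUE))
            msgs <- c(msgs, "non-adapted entries must have zero delay and no insertions")
        pres <- e[!e$abandoned & e$duration > 0, , drop = FALSE]
        if (nrow(pres) > 1L && any(diff(pres$actualOnset) <= 0))
            msgs <- c(msgs, "actual onsets of presented events must be strictly increasing")
    }
    if (length(msgs)) msgs else TRUE
})

#' DesignMatrix: a sampled fMRI design on the scan grid
#'
#' Regressor columns (dynamic regressors, optional temporal derivatives,
#' nuisance covariates and an intercept) sampled at scan times, after
#' discarding \code{ignoreScansAtStart} leading scans.
#'
#' @slot values numeric matrix, (nScans - ignoreScansAtStart) x columns,
#'   with column names.
#' @slot tr repetition time (ms).
#' @slot nScans total scans of the run before discarding.
#' @slot ignoreScansAtStart leading scans discarded.
#'
#' @seealso [buildDesignMatrix()], [fitGlm()]
#' @exportClass DesignMatrix
setClass("DesignMatrix",
    representation(values = "matrix", tr = "numeric", nScans = "integer",
                   ignoreScansAtStart = "integer"),
    prototype(values = matrix(numeric(), 0, 0), tr = 2000,
              nScans = 0L, ignoreScansAtStart = 0L))

setValidity("DesignMatrix", function(object) {
    msgs <- NULL
    if (nrow(object@values) != object@nScans - object@ignoreScansAtStart)
        msgs <- c(msgs, "rows must equal nScans - ignoreScansAtStart")
    if (ncol(object@values) > 0L && is.null(colnames(object@values)))
        msgs <- c(msgs, "columns must be named")
    if (length(msgs)) msgs else TRUE
})

#' GlmFit: ordinary least squares fit of a design to voxel time series
#'
#' @slot beta coefficient matrix, parameters x voxels.
#' @slot sigma2 residual variance per voxel (RSS / dof).
#' @slot dof residual degrees of freedom (rows - rank of the design).
#' @slot xtxInv (pseudo)inverse of the normal-equations matrix, used for
#'   contrast standard errors.
#' @slot rank numeric rank of the design.
#'
#' @seealso [fitGlm()], [contrastTMap()]
#' @exportClass GlmFit
setClass("GlmFit",
    representation(beta = "matrix", sigma2 = "numeric", dof = "integer",
                   xtxInv = "matrix", rank = "integer"))

setValidity("GlmFit", function(object) {
    msgs <- NULL
    if (ncol(object@beta) != length(object@sigma2))
        msgs <- c(msgs, "one sigma2 per voxel required")
    if (nrow(object@beta) != nrow(object@xtxInv))
        msgs <- c(msgs, "xtxInv dimension must match number of parameters")
    if (length(msgs)) msgs else TRUE
})

#' GlmAccumulator: sufficient statistics for an incremental GLM
#'
#' Accumulates the normal-equations blocks X'X, X'Y and the per-voxel sum
#' of squares Y'Y scan by scan, so that a fit after scan k is exactly the
#' batch fit on the first k scans.
#'
#' @slot xtx p x p matrix of accumulated X'X.
#' @slot xty p x voxels matrix of accumulated X'Y.
#' @slot yty per-voxel accumulated squared responses.
#' @slot n scans accumulated so far.
#'
#' @seealso [glmAccumulator()], [addScans()], [glmEstimates()]
#' @exportClass GlmAccumulator
setClass("GlmAccumulator",
    representation(xtx = "matrix", xty = "matrix", yty = "numeric",
                   n = "integer"))
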