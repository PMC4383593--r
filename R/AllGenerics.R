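#' Accessors for flexstim containers
#'
#' Accessor generics for the slots of [ExperimentSpec-class],
#' [EventLog-class], [DesignMatrix-class] and [GlmFit-class] objects.
#'
#' @param object a flexstim container object.
#' @return The corresponding slot value: a data.frame, list, matrix or
#'   scalar as documented on each class.
#' @name accessors
#' @aliases media timetable systemVariables constraints transferFunctions
#'   regressorSpecs ignoreScansAtStart repetitionTime entries runEnd
#'   designMatrix nScans
NULL

#' @rdname accessors
#' @export
setGeneric("media", function(object) standardGeneric("media"))
#' @rdname accessors
#' @export
setGeneric("timetable", function(object) standardGeneric("timetable"))
#' @rdname accessors
#' @export
setGeneric("systemVariables",
           function(object) standardGeneric("systemVariables"))
#' @rdname accessors
#' @export
setGeneric("constraints", function(object) standardGeneric("constraints"))
#' @rdname accessors
#' @export
setGeneric("transferFunctions",
           function(object) standardGeneric("transferFunctions"))
#' @rdname accessors
#' @export
setGeneric("regressorSpecs",
           function(object) standardGeneric("regressorSpecs"))
#' @rdname accessors
#' @export
setGeneric("ignoreScansAtStart",
           function(object) standardGeneric("ignoreScansAtStart"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime",
           function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("runEnd", function(object) standardGeneric("runEnd"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))

#' @rdname addScans
#' @export
setGeneric("addScans", function(object, x, y) standardGeneric("addScans"))
#' @rdname addScans
#' @export
setGeneric("glmEstimates", function(object) standardGeneric("glmEstimates"))

setMethod("media", "ExperimentSpec", function(object) object@media)
setMethod("timetable", "ExperimentSpec", function(object) object@timetable)
setMethod("systemVariables", "ExperimentSpec",
          function(object) object@systemVariables)
setMethod("constraints", "ExperimentSpec", function(object) object@constraints)
setMethod("transferFunctions", "ExperimentSpec",
          function(object) object@transferFunctions)
setMethod("regressorSpecs", "ExperimentSpec",
          function(object) object@regressorSpecs)
setMethod("ignoreScansAtStart", "ExperimentSpec",
          function(object) object@ignoreScansAtStart)
setMethod("repetitionTime", "ExperimentSpec", function(object) object@tr)

setMethod("entries", "EventLog", function(object) object@entries)
setMethod("runEnd", "EventLog", function(object) object@runEnd)

setMethod("designMatrix", "DesignMatrix", function(object) object@values)
setMethod("nScans", "DesignMatrix", function(object) object@nScans)
setMethod("repetitionTime", "DesignMatrix", function(object) object@tr)
setMethod("ignoreScansAtStart", "DesignMatrix",
          function(object) object@ignoreScansAtStart)

#' @importFrom stats coef
#' @export
setMethod("coef", "GlmFit", function(object, ...) object@beta)

setMethod("show", "ExperimentSpec", function(object) {
    cat("ExperimentSpec\n")
    cat(sprintf("  media objects     : %d\n", nrow(object@media)))
    cat(sprintf("  timetable events  : %d\n", nrow(object@timetable)))
    cat(sprintf("  system variables  : %d\n", nrow(object@systemVariables)))
    cat(sprintf("  constraints       : %d\n", length(object@constraints)))
    cat(sprintf("  transfer functions: %d\n", nrow(object@transferFunctions)))
    cat(sprintf("  dynamic regressors: %d\n", nrow(object@regressorSpecs)))
    cat(sprintf("  TR %g ms, ignoreScansAtStart %d\n",
                object@tr, object@ignoreScansAtStart))
})

setMethod("show", "EventLog", function(object) {
    e <- object@entries
    cat("EventLog\n")
    cat(sprintf("  entries : %d (%d inserted fillers)\n",
                nrow(e), sum(e$inserted)))
    if (any(e$adapted))
        cat(sprintf("  adapted : %d, mean delay %.1f ms\n",
                    sum(e$adapted), mean(e$delay[e$adapted])))
    cat(sprintf("  run end : %g ms\n", object@runEnd))
})

setMethod("show", "DesignMatrix", function(object) {
    cat(sprintf("DesignMatrix: %d scans x %d columns (TR %g ms, %d leading scans discarded)\n",
                nrow(object@values), ncol(object@values), object@tr,
                object@ignoreScansAtStart))
    cat("  columns:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "GlmFit", function(object) {
    cat(sprintf("GlmFit: %d parameters x %d voxels, dof %d (rank %d)\n",
                nrow(object@beta), ncol(object@beta), object@dof,
                object@rank))
})
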