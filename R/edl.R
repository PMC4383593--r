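## Experiment-description dialect: an XML format describing media objects,
## a presentation timetable, and the adaptive constructs (system variables,
## constraints with stimulus actions, transfer functions, dynamic
## time-based regressors). Whitespace around attribute '=' signs and
## attribute order are insignificant; times are integer milliseconds.

.KINDS <- c(image = "IMAGE", text = "TEXT", audio = "AUDIO")

.parseNum <- function(x, what, id = NULL) {
    if (is.null(x) || is.na(x)) return(NA_real_)
    out <- suppressWarnings(as.numeric(x))
    if (is.na(out))
        stop(sprintf("malformed numeric value '%s' for %s%s", x, what,
                     if (is.null(id)) "" else sprintf(" of '%s'", id)),
             call. = FALSE)
    out
}

.parseBool <- function(x, default = FALSE) {
    if (is.null(x) || is.na(x)) return(default)
    tolower(x) %in% c("true", "1", "yes")
}

.fmtNum <- function(x) format(x, scientific = FALSE, trim = TRUE)
.fmtBool <- function(x) ifelse(x, "true", "false")

#' Construct an experiment specification
#'
#' Low-level constructor assembling an [ExperimentSpec-class] from its
#' component tables. Most users will obtain specifications from
#' [parseExperiment()] or [generateSchedule()] instead. The timetable is
#' stably sorted by onset. No cross-reference checking is performed here;
#' use [validateRules()].
#'
#' @param media,timetable,systemVariables,transferFunctions,regressorSpecs
#'   data.frames with the columns documented on [ExperimentSpec-class];
#'   missing optional columns are filled with defaults.
#' @param constraints named list of constraints, see [newConstraint()].
#' @param ignoreScansAtStart integer, leading scans discarded before GLM.
#' @param tr repetition time in milliseconds.
#' @return An [ExperimentSpec-class] object.
#' @export
experimentSpec <- function(media = .emptyMedia(),
                           timetable = .emptyTimetable(),
                           systemVariables = .emptySystemVariables(),
                           constraints = list(),
                           transferFunctions = .emptyTransferFunctions(),
                           regressorSpecs = .emptyRegressorSpecs(),
                           ignoreScansAtStart = 0L, tr = 2000) {
    media <- .fillColumns(media, .emptyMedia())
    timetable <- .fillColumns(timetable, .emptyTimetable())
    timetable <- timetable[order(timetable$onset), , drop = FALSE]
    rownames(timetable) <- NULL
    if (length(constraints) && is.null(names(constraints)))
        names(constraints) <- vapply(constraints, `[[`, "", "id")
    new("ExperimentSpec", media = media, timetable = timetable,
        systemVariables = .fillColumns(systemVariables,
                                       .emptySystemVariables()),
        constraints = constraints,
        transferFunctions = .fillColumns(transferFunctions,
                                         .emptyTransferFunctions()),
        regressorSpecs = .fillColumns(regressorSpecs, .emptyRegressorSpecs()),
        ignoreScansAtStart = as.integer(ignoreScansAtStart), tr = tr)
}

.fillColumns <- function(df, template) {
    for (nm in colnames(template))
        if (is.null(df[[nm]]))  # typed NA matching the template column
            df[[nm]] <- rep(template[[nm]][NA_integer_], nrow(df))
    rownames(df) <- NULL
    df[, colnames(template), drop = FALSE]
}

#' Constraint and stimulus-action constructors
#'
#' A constraint gates the presentation of the media objects that reference
#' it: its conditions (system-variable references) are evaluated as a
#' conjunction at the event's onset, and the `actionsThen` or `actionsElse`
#' list of stimulus actions is executed depending on the result. The three
#' stimulus actions mirror the adaptive repertoire: insert a new event
#' (optionally shifting all following events by its duration), replace the
#' stimulus of the pending event, or adapt its presentation position.
#'
#' @param id constraint identifier.
#' @param conditions character vector of system-variable ids, combined as
#'   logical AND; the empty conjunction evaluates true.
#' @param actionsThen,actionsElse lists of stimulus actions executed when
#'   the conjunction is true / false.
#' @param duration filler duration in ms (must be positive).
#' @param mediaRef id of the media object to insert or substitute.
#' @param shiftFollowing logical; shift every following event by `duration`.
#' @param posX,posY new presentation coordinates.
#' @param absolute logical; if `FALSE`, `posX`/`posY` are deltas.
#' @return `newConstraint()` returns a constraint list; the action
#'   constructors return action lists understood by [applyAction()] and
#'   [runClosedLoop()].
#' @export
newConstraint <- function(id, conditions = character(),
                          actionsThen = list(), actionsElse = list()) {
    list(id = id, conditions = as.character(conditions),
         actionsThen = actionsThen, actionsElse = actionsElse)
}

#' @rdname newConstraint
#' @export
insertEventAction <- function(duration, mediaRef, shiftFollowing = TRUE) {
    stopifnot(duration > 0)
    list(type = "insertEvent", duration = as.numeric(duration),
         mediaRef = mediaRef, shiftFollowing = isTRUE(shiftFollowing))
}

#' @rdname newConstraint
#' @export
replaceStimulusAction <- function(mediaRef) {
    list(type = "replaceStimulus", mediaRef = mediaRef)
}

#' @rdname newConstraint
#' @export
adaptParamsAction <- function(posX, posY, absolute = TRUE) {
    list(type = "adaptParams", posX = as.numeric(posX),
         posY = as.numeric(posY), absolute = isTRUE(absolute))
}

## ---- parsing ----------------------------------------------------------

.parseAction <- function(node) {
    child <- xml2::xml_children(node)
    if (length(child) != 1L)
        stop("each <stimulusAction> must contain exactly one action element",
             call. = FALSE)
    child <- child[[1L]]
    a <- xml2::xml_attrs(child)
    switch(xml2::xml_name(child),
        insertNewStimulusEvent = insertEventAction(
            .parseNum(a[["duration"]], "duration"),
            a[["mediaObjectRef"]],
            .parseBool(a["shiftFollowingStimulusEvents"])),
        replaceStimulus = replaceStimulusAction(a[["mediaObjectRef"]]),
        adaptPresentationParameters = adaptParamsAction(
            .parseNum(a[["posX"]], "posX"), .parseNum(a[["posY"]], "posY"),
            !identical(unname(a["mode"]), "relative")),
        stop(sprintf("unknown stimulus action '%s'", xml2::xml_name(child)),
             call. = FALSE))
}

.attrOrNA <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.null(v)) NA_character_ else v
}

#' Parse an experiment description document
#'
#' Reads an XML experiment description — media objects, timetable, system
#' variables, constraints with stimulus actions, transfer functions and
#' dynamic time-based regressors — into an [ExperimentSpec-class].
#'
#' @param x path to an XML file, or a single string holding the document.
#' @param lengthUnit unit of the `maxLength`/`length` attributes of the
#'   dynamic design structure: `"ms"` (default) or `"us"`.
#' @param validate if `TRUE` (default), [validateRules()] is run and any
#'   violation raises an error naming the offending identifier.
#' @return An [ExperimentSpec-class] object.
#' @examples
#' xml <- writeExperiment(experimentSpec(tr = 2000))
#' spec <- parseExperiment(xml)
#' @seealso [validateRules()], [writeExperiment()]
#' @export
parseExperiment <- function(x, lengthUnit = c("ms", "us"), validate = TRUE) {
    lengthUnit <- match.arg(lengthUnit)
    lenScale <- if (lengthUnit == "us") 1e-3 else 1
    doc <- xml2::read_xml(x)

    mo <- xml2::xml_find_all(doc, ".//mediaObject")
    media <- do.call(rbind, c(list(.emptyMedia()), lapply(mo, function(m) {
        kind <- names(.KINDS)[match(toupper(xml2::xml_attr(m, "type")),
                                    .KINDS)]
        if (is.na(kind))
            stop(sprintf("unknown media type '%s' for '%s'",
                         xml2::xml_attr(m, "type"),
                         xml2::xml_attr(m, "moID")), call. = FALSE)
        content <- switch(kind,
            image = xml2::xml_find_first(m, "./contentImage"),
            text = xml2::xml_find_first(m, "./contentText"),
            audio = xml2::xml_find_first(m, "./contentAudio"))
        ref <- switch(kind,
            image = xml2::xml_text(xml2::xml_find_first(content,
                                                        "./imageFile")),
            text = xml2::xml_text(xml2::xml_find_first(content, "./text")),
            audio = xml2::xml_text(xml2::xml_find_first(content,
                                                        "./audioFile")))
        px <- xml2::xml_find_first(content, "./posX")
        py <- xml2::xml_find_first(content, "./posY")
        ra <- xml2::xml_find_first(m, "./regressorAssignment")
        id <- xml2::xml_attr(m, "moID")
        data.frame(id = id, name = xml2::xml_attr(m, "name"), kind = kind,
            contentRef = ref,
            posX = if (inherits(px, "xml_missing")) 0
                   else .parseNum(xml2::xml_text(px), "posX", id),
            posY = if (inherits(py, "xml_missing")) 0
                   else .parseNum(xml2::xml_text(py), "posY", id),
            constraintRef = .attrOrNA(m, "useConstraint"),
            regressorRef = if (inherits(ra, "xml_missing")) NA_character_
                           else xml2::xml_attr(ra, "assignToRegressor"),
            transferFunctionRef = if (inherits(ra, "xml_missing"))
                NA_character_ else xml2::xml_attr(ra, "useTransferFunction"),
            stringsAsFactors = FALSE)
    })))

    ev <- xml2::xml_find_all(doc, ".//timeTable/stimEvent")
    timetable <- do.call(rbind, c(list(.emptyTimetable()),
        lapply(ev, function(e) {
            ref <- xml2::xml_attr(e, "mediaObjectRef")
            data.frame(onset = .parseNum(xml2::xml_attr(e, "onset"),
                                         "onset", ref),
                       duration = .parseNum(xml2::xml_attr(e, "duration"),
                                            "duration", ref),
                       mediaRef = ref, stringsAsFactors = FALSE)
        })))

    sv <- xml2::xml_find_all(doc, ".//systemVariable")
    sysvars <- do.call(rbind, c(list(.emptySystemVariables()),
        lapply(sv, function(s) data.frame(
            source = xml2::xml_attr(s, "source"),
            id = xml2::xml_attr(s, "systemVariableID"),
            name = xml2::xml_attr(s, "systemVariableName"),
            stringsAsFactors = FALSE))))

    co <- xml2::xml_find_all(doc, ".//constraint")
    constraintList <- lapply(co, function(cn) {
        conds <- xml2::xml_attr(
            xml2::xml_find_all(cn, "./conditions/condition"),
            "systemVariableRef")
        thenA <- lapply(xml2::xml_find_all(
            cn, "./stimulusActions_then/stimulusAction"), .parseAction)
        elseA <- lapply(xml2::xml_find_all(
            cn, "./stimulusActions_else/stimulusAction"), .parseAction)
        newConstraint(xml2::xml_attr(cn, "constraintID"), conds,
                      thenA, elseA)
    })

    tf <- xml2::xml_find_all(doc, ".//transferFunction")
    tfs <- do.call(rbind, c(list(.emptyTransferFunctions()),
        lapply(tf, function(f) {
            id <- xml2::xml_attr(f, "transferFunctionID")
            data.frame(id = id,
                timeOffset = .parseNum(xml2::xml_attr(f, "timeOffset"),
                                       "timeOffset", id),
                durationScale = .parseNum(
                    xml2::xml_attr(f, "durationScaleFactor"),
                    "durationScaleFactor", id),
                parametricScale = .parseNum(
                    xml2::xml_attr(f, "parametricScaleFactor"),
                    "parametricScaleFactor", id),
                stringsAsFactors = FALSE)
        })))

    rg <- xml2::xml_find_all(doc, ".//dynamicTimeBasedRegressor")
    regs <- do.call(rbind, c(list(.emptyRegressorSpecs()),
        lapply(rg, function(r) {
            id <- xml2::xml_attr(r, "regressorID")
            data.frame(id = id, name = xml2::xml_attr(r, "name"),
                maxLength = .parseNum(xml2::xml_attr(r, "length"),
                                      "length", id) * lenScale,
                refFct = xml2::xml_attr(r, "useRefFct"),
                firstDerivative = .parseBool(
                    xml2::xml_attr(r, "useRefFctFirstDerivative")),
                secondDerivative = .parseBool(
                    xml2::xml_attr(r, "useRefFctSecondDerivative")),
                zeroMean = .parseBool(
                    xml2::xml_attr(r, "scaleHeightToZeroMean")),
                stringsAsFactors = FALSE)
        })))

    par <- xml2::xml_find_first(doc, ".//paradigm")
    ignore <- 0L
    tr <- 2000
    if (!inherits(par, "xml_missing")) {
        ig <- xml2::xml_attr(par, "ignoreScansAtStart")
        if (!is.na(ig))
            ignore <- as.integer(.parseNum(ig, "ignoreScansAtStart"))
        trA <- xml2::xml_attr(par, "tr")
        if (!is.na(trA)) tr <- .parseNum(trA, "tr")
    }

    spec <- experimentSpec(media = media, timetable = timetable,
                           systemVariables = sysvars,
                           constraints = constraintList,
                           transferFunctions = tfs, regressorSpecs = regs,
                           ignoreScansAtStart = ignore, tr = tr)
    if (validate) {
        v <- validateRules(spec)
        if (length(v))
            stop("invalid experiment description:\n  ",
                 paste(v, collapse = "\n  "), call. = FALSE)
    }
    spec
}

## ---- rule validation --------------------------------------------------

#' Check the consistency rules of an experiment specification
#'
#' Walks every cross-reference and invariant of the specification and
#' returns the violations found, one human-readable message per problem,
#' each naming the offending identifier. An empty character vector means
#' the specification is consistent.
#'
#' Checked rules: identifier uniqueness (media, system variables,
#' constraints, transfer functions, regressors, and (source, name) pairs);
#' resolvability of constraint, regressor and transfer-function references
#' on media objects (a regressor assignment needs both ends); timetable
#' events referencing declared media with non-negative onset and duration;
#' constraint conditions referencing declared system variables; action
#' media references; positive insert durations, positive regressor
#' lengths, non-negative duration scale factors.
#'
#' @param spec an [ExperimentSpec-class].
#' @return character vector of violation messages (empty if valid).
#' @export
validateRules <- function(spec) {
    v <- character()
    bad <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))
    m <- spec@media; tt <- spec@timetable; sv <- spec@systemVariables
    tf <- spec@transferFunctions; rg <- spec@regressorSpecs
    cs <- spec@constraints

    for (d in m$id[duplicated(m$id)]) bad("duplicate media id '%s'", d)
    for (d in sv$id[duplicated(sv$id)])
        bad("duplicate system variable id '%s'", d)
    pair <- paste(sv$source, sv$name, sep = "::")
    for (d in pair[duplicated(pair)])
        bad("duplicate system variable (source, name) pair '%s'", d)
    cids <- vapply(cs, `[[`, "", "id")
    for (d in cids[duplicated(cids)]) bad("duplicate constraint id '%s'", d)
    for (d in tf$id[duplicated(tf$id)])
        bad("duplicate transfer function id '%s'", d)
    for (d in rg$id[duplicated(rg$id)]) bad("duplicate regressor id '%s'", d)

    for (i in seq_len(nrow(m))) {
        cr <- m$constraintRef[i]
        if (!is.na(cr) && !(cr %in% cids))
            bad("media '%s' references undeclared constraint '%s'",
                m$id[i], cr)
        rr <- m$regressorRef[i]; tr <- m$transferFunctionRef[i]
        if (!is.na(rr) || !is.na(tr)) {
            if (is.na(rr) || is.na(tr))
                bad("media '%s' has an incomplete regressor assignment",
                    m$id[i])
            if (!is.na(rr) && !(rr %in% rg$id))
                bad("media '%s' references undeclared regressor '%s'",
                    m$id[i], rr)
            if (!is.na(tr) && !(tr %in% tf$id))
                bad("media '%s' references undeclared transfer function '%s'",
                    m$id[i], tr)
        }
    }

    for (i in seq_len(nrow(tt))) {
        if (!(tt$mediaRef[i] %in% m$id))
            bad("timetable event %d references undeclared media '%s'",
                i, tt$mediaRef[i])
        if (is.na(tt$onset[i]) || tt$onset[i] < 0)
            bad("timetable event %d ('%s') has negative onset",
                i, tt$mediaRef[i])
        if (is.na(tt$duration[i]) || tt$duration[i] < 0)
            bad("timetable event %d ('%s') has negative duration",
                i, tt$mediaRef[i])
    }

    checkAction <- function(a, cid) {
        if (a$type %in% c("insertEvent", "replaceStimulus") &&
            !(a$mediaRef %in% m$id))
            bad("constraint '%s' action references undeclared media '%s'",
                cid, a$mediaRef)
        if (a$type == "insertEvent" && a$duration <= 0)
            bad("constraint '%s' insert action has non-positive duration",
                cid)
    }
    for (cn in cs) {
        for (cond in cn$conditions)
            if (!(cond %in% sv$id))
                bad("constraint '%s' condition references undeclared system variable '%s'",
                    cn$id, cond)
        for (a in cn$actionsThen) checkAction(a, cn$id)
        for (a in cn$actionsElse) checkAction(a, cn$id)
    }

    for (i in seq_len(nrow(rg)))
        if (is.na(rg$maxLength[i]) || rg$maxLength[i] <= 0)
            bad("regressor '%s' must have positive length", rg$id[i])
    for (i in seq_len(nrow(tf)))
        if (is.na(tf$durationScale[i]) || tf$durationScale[i] < 0)
            bad("transfer function '%s' has negative duration scale",
                tf$id[i])
    v
}

## ---- serialization ----------------------------------------------------

.actionNode <- function(parent, a) {
    sa <- xml2::xml_add_child(parent, "stimulusAction")
    switch(a$type,
        insertEvent = xml2::xml_add_child(sa, "insertNewStimulusEvent",
            duration = .fmtNum(a$duration), mediaObjectRef = a$mediaRef,
            shiftFollowingStimulusEvents = .fmtBool(a$shiftFollowing)),
        replaceStimulus = xml2::xml_add_child(sa, "replaceStimulus",
            mediaObjectRef = a$mediaRef),
        adaptParams = xml2::xml_add_child(sa,
            "adaptPresentationParameters", posX = .fmtNum(a$posX),
            posY = .fmtNum(a$posY),
            mode = if (a$absolute) "absolute" else "relative"))
    invisible(sa)
}

#' Serialize an experiment specification to XML
#'
#' Writes the dialect read by [parseExperiment()]; parsing the output
#' yields an object equal to `spec` on all modelled fields (round-trip
#' identity).
#'
#' @param spec an [ExperimentSpec-class].
#' @param path optional file path; when given the document is written
#'   there and the path returned invisibly.
#' @return The XML document as a single string (or invisibly the path).
#' @export
writeExperiment <- function(spec, path = NULL) {
    doc <- xml2::xml_new_root("experiment")

    cwrap <- xml2::xml_add_child(doc, "constraints")
    svs <- xml2::xml_add_child(cwrap, "systemVariables")
    sv <- spec@systemVariables
    for (i in seq_len(nrow(sv)))
        xml2::xml_add_child(svs, "systemVariable", source = sv$source[i],
                            systemVariableID = sv$id[i],
                            systemVariableName = sv$name[i])
    for (cn in spec@constraints) {
        cnode <- xml2::xml_add_child(cwrap, "constraint",
                                     constraintID = cn$id)
        conds <- xml2::xml_add_child(cnode, "conditions")
        for (cond in cn$conditions)
            xml2::xml_add_child(conds, "condition",
                                systemVariableRef = cond)
        if (length(cn$actionsThen)) {
            tn <- xml2::xml_add_child(cnode, "stimulusActions_then")
            for (a in cn$actionsThen) .actionNode(tn, a)
        }
        if (length(cn$actionsElse)) {
            en <- xml2::xml_add_child(cnode, "stimulusActions_else")
            for (a in cn$actionsElse) .actionNode(en, a)
        }
    }

    mwrap <- xml2::xml_add_child(doc, "mediaObjects")
    m <- spec@media
    for (i in seq_len(nrow(m))) {
        attrs <- list(moID = m$id[i], name = m$name[i],
                      type = .KINDS[[m$kind[i]]])
        if (!is.na(m$constraintRef[i]))
            attrs$useConstraint <- m$constraintRef[i]
        mn <- do.call(xml2::xml_add_child,
                      c(list(mwrap, "mediaObject"), attrs))
        cont <- xml2::xml_add_child(mn, switch(m$kind[i],
            image = "contentImage", text = "contentText",
            audio = "contentAudio"))
        fileNode <- switch(m$kind[i], image = "imageFile", text = "text",
                           audio = "audioFile")
        xml2::xml_add_child(cont, fileNode, m$contentRef[i])
        xml2::xml_add_child(cont, "posX", .fmtNum(m$posX[i]))
        xml2::xml_add_child(cont, "posY", .fmtNum(m$posY[i]))
        if (!is.na(m$regressorRef[i]))
            xml2::xml_add_child(mn, "regressorAssignment",
                assignToRegressor = m$regressorRef[i],
                useTransferFunction = m$transferFunctionRef[i])
    }

    tt <- spec@timetable
    tnode <- xml2::xml_add_child(doc, "timeTable")
    for (i in seq_len(nrow(tt)))
        xml2::xml_add_child(tnode, "stimEvent",
                            onset = .fmtNum(tt$onset[i]),
                            duration = .fmtNum(tt$duration[i]),
                            mediaObjectRef = tt$mediaRef[i])

    tfnode <- xml2::xml_add_child(doc, "transferFunctions")
    tf <- spec@transferFunctions
    for (i in seq_len(nrow(tf)))
        xml2::xml_add_child(tfnode, "transferFunction",
            transferFunctionID = tf$id[i],
            timeOffset = .fmtNum(tf$timeOffset[i]),
            durationScaleFactor = .fmtNum(tf$durationScale[i]),
            parametricScaleFactor = .fmtNum(tf$parametricScale[i]))

    par <- xml2::xml_add_child(doc, "paradigm",
        ignoreScansAtStart = .fmtNum(spec@ignoreScansAtStart),
        tr = .fmtNum(spec@tr))
    rg <- spec@regressorSpecs
    if (nrow(rg)) {
        dds <- xml2::xml_add_child(par, "dynamicDesignStruct",
                                   maxLength = .fmtNum(max(rg$maxLength)))
        for (i in seq_len(nrow(rg)))
            xml2::xml_add_child(dds, "dynamicTimeBasedRegressor",
                length = .fmtNum(rg$maxLength[i]), name = rg$name[i],
                regressorID = rg$id[i],
                scaleHeightToZeroMean = .fmtBool(rg$zeroMean[i]),
                useRefFct = rg$refFct[i],
                useRefFctFirstDerivative = .fmtBool(rg$firstDerivative[i]),
                useRefFctSecondDerivative = .fmtBool(rg$secondDerivative[i]))
    }

    txt <- as.character(doc)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(path))
    }
    txt
}
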