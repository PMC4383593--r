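## Discrete-time closed-loop engine. Time is simulated (integer-ms master
## clock); correctness is about event times, not wall time. A constrained
## event is evaluated at its (possibly shifted) onset; on failure one
## else-action set executes — typically "insert a short filler and shift
## everything that follows" — and the constraint is re-evaluated at the end
## of the filler, until it holds or `stop` is reached.

#' Evaluate a constraint against registered providers
#'
#' Looks up each condition's system variable, queries the provider
#' registered for its source at time `t`, and combines the values as a
#' conjunction. The empty condition list evaluates true.
#'
#' @param constraint a constraint (see [newConstraint()]).
#' @param providers named list mapping source identifiers to provider
#'   functions `function(varName, t)`; see [gazeProvider()].
#' @param t evaluation time (ms).
#' @param systemVariables the system-variable table of the experiment
#'   ([systemVariables()]).
#' @return list with elements `result` (logical) and `actions` (the
#'   then-actions if true, else-actions if false).
#' @export
evaluateConstraint <- function(constraint, providers, t, systemVariables) {
    result <- TRUE
    for (cid in constraint$conditions) {
        row <- match(cid, systemVariables$id)
        if (is.na(row))
            stop(sprintf("condition references undeclared system variable '%s'",
                         cid), call. = FALSE)
        src <- systemVariables$source[row]
        provider <- providers[[src]]
        if (is.null(provider))
            stop(sprintf("no provider registered for source '%s'", src),
                 call. = FALSE)
        result <- result && isTRUE(provider(systemVariables$name[row], t))
        if (!result) break
    }
    list(result = result,
         actions = if (result) constraint$actionsThen
                   else constraint$actionsElse)
}

#' Insert an event into a timetable, optionally shifting what follows
#'
#' Inserts a new event at time `at`. When the action requests shifting,
#' every event with onset greater than or equal to `at` is moved later by
#' exactly the inserted duration, so pairwise gaps among shifted events
#' are unchanged; otherwise no existing onset changes.
#'
#' @param timetable data.frame with columns onset, duration, mediaRef.
#' @param at insertion time (ms); must not exceed the onset of any event
#'   still to be released.
#' @param action an [insertEventAction()].
#' @return The updated timetable, sorted by onset.
#' @export
insertAndShift <- function(timetable, at, action) {
    stopifnot(identical(action$type, "insertEvent"))
    if (action$shiftFollowing) {
        move <- timetable$onset >= at
        timetable$onset[move] <- timetable$onset[move] + action$duration
    }
    row <- timetable[0, , drop = FALSE][NA_integer_, , drop = FALSE]
    row$onset <- at
    row$duration <- action$duration
    row$mediaRef <- action$mediaRef
    out <- rbind(timetable, row)
    out <- out[order(out$onset), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Apply a replace or reposition action to a pending event
#'
#' `replaceStimulus` swaps the media reference of the event, leaving its
#' timing untouched; `adaptParams` sets (or, in relative mode, offsets)
#' the event-level presentation position, stored in `posX`/`posY` columns
#' added to the timetable.
#'
#' @param timetable timetable data.frame.
#' @param i row index of the (not yet released) event.
#' @param action a [replaceStimulusAction()] or [adaptParamsAction()].
#' @param media optional media table used to check that a replacement
#'   exists and to supply default positions.
#' @return The updated timetable.
#' @export
applyAction <- function(timetable, i, action, media = NULL) {
    switch(action$type,
        replaceStimulus = {
            if (!is.null(media) && !(action$mediaRef %in% media$id))
                stop(sprintf("replacement references unknown media '%s'",
                             action$mediaRef), call. = FALSE)
            timetable$mediaRef[i] <- action$mediaRef
        },
        adaptParams = {
            if (is.null(timetable$posX)) {
                timetable$posX <- NA_real_
                timetable$posY <- NA_real_
            }
            if (action$absolute) {
                timetable$posX[i] <- action$posX
                timetable$posY[i] <- action$posY
            } else {
                base <- c(timetable$posX[i], timetable$posY[i])
                if (anyNA(base) && !is.null(media)) {
                    j <- match(timetable$mediaRef[i], media$id)
                    base <- c(media$posX[j], media$posY[j])
                }
                base[is.na(base)] <- 0
                timetable$posX[i] <- base[1] + action$posX
                timetable$posY[i] <- base[2] + action$posY
            }
        },
        stop(sprintf("applyAction cannot execute action type '%s'",
                     action$type), call. = FALSE))
    timetable
}

## growing column buffers: amortized O(1) appends for long filler logs
.newLogBuffer <- function(capacity = 256L) {
    env <- new.env(parent = emptyenv())
    env$n <- 0L
    env$cap <- capacity
    env$mediaRef <- character(capacity)
    env$plannedOnset <- numeric(capacity)
    env$actualOnset <- numeric(capacity)
    env$duration <- numeric(capacity)
    env$delay <- numeric(capacity)
    env$adapted <- logical(capacity)
    env$validAtOnset <- logical(capacity)
    env$nInsertions <- integer(capacity)
    env$inserted <- logical(capacity)
    env$abandoned <- logical(capacity)
    env
}

.logPush <- function(b, mediaRef, plannedOnset, actualOnset, duration,
                     delay, adapted, validAtOnset, nInsertions, inserted,
                     abandoned) {
    if (b$n == b$cap) {
        b$cap <- b$cap * 2L
        for (nm in names(.logColumns)) length(b[[nm]]) <- b$cap
    }
    i <- b$n + 1L
    b$mediaRef[i] <- mediaRef; b$plannedOnset[i] <- plannedOnset
    b$actualOnset[i] <- actualOnset; b$duration[i] <- duration
    b$delay[i] <- delay; b$adapted[i] <- adapted
    b$validAtOnset[i] <- validAtOnset; b$nInsertions[i] <- nInsertions
    b$inserted[i] <- inserted; b$abandoned[i] <- abandoned
    b$n <- i
    invisible(b)
}

.logCollect <- function(b) {
    idx <- seq_len(b$n)
    out <- data.frame(mediaRef = b$mediaRef[idx],
                      plannedOnset = b$plannedOnset[idx],
                      actualOnset = b$actualOnset[idx],
                      duration = b$duration[idx], delay = b$delay[idx],
                      adapted = b$adapted[idx],
                      validAtOnset = b$validAtOnset[idx],
                      nInsertions = b$nInsertions[idx],
                      inserted = b$inserted[idx],
                      abandoned = b$abandoned[idx],
                      stringsAsFactors = FALSE)
    out
}

#' Run an adaptive experiment against system-variable providers
#'
#' Releases the timetable in onset order. Unconstrained events are
#' presented at their planned onsets. For an event whose media object
#' carries a constraint, the constraint is evaluated at the event's
#' current onset: if it holds, the then-actions (if any) are applied and
#' the event is presented; if not, the else-actions execute — an
#' insert-event action presents a filler and moves the pending event (and,
#' when shifting, all following events) behind it — and the constraint is
#' re-evaluated at the end of the filler. The loop continues until the
#' constraint holds or `stop` is exceeded, in which case the event is
#' logged as abandoned and the engine terminates cleanly.
#'
#' @param spec an [ExperimentSpec-class].
#' @param providers named list of provider functions keyed by source
#'   identifier (see [evaluateConstraint()]).
#' @param stop latest permissible presentation time (ms); default
#'   unbounded.
#' @return An [EventLog-class]; filler presentations are included as
#'   entries with `inserted = TRUE`.
#' @examples
#' spec <- generateSchedule(syntheticRatings(2, 2, seed = 1), seed = 1)
#' gaze <- simulateGaze(gazeModel(compliance = 1), duration = 60000,
#'                      seed = 1)
#' log <- runClosedLoop(spec, list(org.flexstim.gaze = gazeProvider(gaze)))
#' @seealso [gazeProvider()], [compliance()]
#' @export
runClosedLoop <- function(spec, providers, stop = Inf) {
    tt <- spec@timetable
    m <- spec@media
    sysvars <- spec@systemVariables
    cons <- spec@constraints
    constraintOf <- m$constraintRef[match(tt$mediaRef, m$id)]

    onset <- tt$onset
    planned <- tt$onset
    duration <- tt$duration
    mref <- tt$mediaRef
    n <- length(onset)
    buf <- .newLogBuffer()
    runEnd <- 0

    for (i in seq_len(n)) {
        t <- onset[i]
        ## the plan as it stands when the event comes up for release:
        ## shifts caused by earlier events are part of the plan, so delay
        ## measures only this event's own waiting
        planned[i] <- t
        cid <- constraintOf[i]
        if (is.na(cid)) {
            abandoned <- t > stop
            .logPush(buf, mref[i], planned[i], t, duration[i], 0, FALSE,
                     NA, 0L, FALSE, abandoned)
            if (!abandoned) runEnd <- max(runEnd, t + duration[i])
            next
        }
        constraint <- cons[[cid]]
        if (is.null(constraint))  # base:: since `stop` is an argument here
            base::stop(sprintf("media '%s' references undeclared constraint '%s'",
                               mref[i], cid), call. = FALSE)
        nIns <- 0L
        valid <- FALSE
        abandoned <- FALSE
        repeat {
            if (t > stop) { abandoned <- TRUE; break }
            ev <- evaluateConstraint(constraint, providers, t, sysvars)
            acts <- ev$actions
            if (ev$result) {
                for (a in acts) {
                    if (a$type == "insertEvent") {
                        ## then-branch insert goes after the current event
                        ## and cannot delay it
                        at <- t + duration[i]
                        .logPush(buf, a$mediaRef, at, at, a$duration, 0,
                                 FALSE, NA, 0L, TRUE, FALSE)
                        runEnd <- max(runEnd, at + a$duration)
                        if (a$shiftFollowing && i < n) {
                            idx <- seq.int(i + 1L, n)
                            sel <- idx[onset[idx] >= at]
                            onset[sel] <- onset[sel] + a$duration
                        }
                    } else {
                        tt <- applyAction(tt, i, a, m)
                    }
                }
                mref[i] <- tt$mediaRef[i]
                valid <- TRUE
                break
            }
            retried <- FALSE
            for (a in acts) {
                if (a$type == "insertEvent") {
                    .logPush(buf, a$mediaRef, t, t, a$duration, 0, FALSE,
                             NA, 0L, TRUE, FALSE)
                    runEnd <- max(runEnd, t + a$duration)
                    nIns <- nIns + 1L
                    if (a$shiftFollowing) {
                        move <- seq.int(i, n)
                        onset[move] <- onset[move] + a$duration
                    } else {
                        onset[i] <- onset[i] + a$duration
                    }
                    t <- onset[i]
                    retried <- TRUE
                } else {
                    tt <- applyAction(tt, i, a, m)
                    mref[i] <- tt$mediaRef[i]
                }
            }
            if (!retried) break  # no retry mechanism: present as invalid
        }
        .logPush(buf, mref[i], planned[i], t, duration[i],
                 if (abandoned) NA_real_ else t - planned[i], TRUE,
                 if (abandoned) NA else valid, nIns, FALSE, abandoned)
        if (!abandoned) runEnd <- max(runEnd, t + duration[i])
    }

    e <- .logCollect(buf)
    e <- e[order(e$actualOnset, e$inserted, method = "radix"), ,
           drop = FALSE]
    rownames(e) <- NULL
    new("EventLog", entries = e, runEnd = runEnd)
}

#' Read and write event logs as tab-separated text
#'
#' The on-disk format follows the BIDS events convention: columns
#' `onset` and `duration` in seconds, `trial_type` (the media identifier),
#' plus `planned_onset`, `delay` (seconds), `adapted`, `valid`,
#' `n_insertions`, `inserted` and `abandoned`.
#'
#' @param log an [EventLog-class].
#' @param path file path of the TSV.
#' @return `writeEventLog()` returns `path` invisibly; `readEventLog()`
#'   returns an [EventLog-class].
#' @export
writeEventLog <- function(log, path) {
    e <- log@entries
    out <- data.frame(onset = e$actualOnset / 1000,
                      duration = e$duration / 1000,
                      trial_type = e$mediaRef,
                      planned_onset = e$plannedOnset / 1000,
                      delay = e$delay / 1000,
                      adapted = e$adapted, valid = e$validAtOnset,
                      n_insertions = e$nInsertions, inserted = e$inserted,
                      abandoned = e$abandoned, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "n/a")
    invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
    d <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
    e <- data.frame(mediaRef = as.character(d$trial_type),
                    plannedOnset = d$planned_onset * 1000,
                    actualOnset = d$onset * 1000,
                    duration = d$duration * 1000, delay = d$delay * 1000,
                    adapted = as.logical(d$adapted),
                    validAtOnset = as.logical(d$valid),
                    nInsertions = as.integer(d$n_insertions),
                    inserted = as.logical(d$inserted),
                    abandoned = as.logical(d$abandoned),
                    stringsAsFactors = FALSE)
    pres <- !e$abandoned
    runEnd <- if (any(pres)) max(e$actualOnset[pres] + e$duration[pres])
              else 0
    new("EventLog", entries = e, runEnd = runEnd)
}
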