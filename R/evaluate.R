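## Offline run analyses: recompute trial validity from the raw gaze
## stream with the same centre-fixation definition the engine used online
## (which doubles as a validation of the online adaptation), split
## subjects on fixation performance, and compare how fast each condition
## accumulates valid trials.

#' Offline fixation-compliance report for a run
#'
#' Recomputes the validity of every presented picture trial from the raw
#' gaze stream with [isFixated()] at the actual onset — the same
#' definition the closed-loop engine used online, so for adapted trials
#' the offline flags must reproduce the logged `validAtOnset` flags
#' exactly. Trials whose onset window is not covered by the gaze stream
#' are marked indeterminate and excluded from denominators.
#'
#' @param log an [EventLog-class].
#' @param gaze the gaze stream of the run.
#' @param params a [fixationParams()].
#' @return list of class `complianceReport`: `trials` (per-trial table
#'   with condition, onset, offline validity, indeterminate flag, gaze
#'   distance from centre at onset, delay), `summary` (per-condition
#'   trial counts, valid fraction, mean distance, mean adapted delay,
#'   indeterminate count), `onlineConsistent` (logical: offline flags
#'   equal online flags on all determinate adapted trials), and
#'   `nonAdaptedValidFraction` (the subject's fixation-performance score
#'   used for group splitting).
#' @seealso [medianSplit()], [timeToValid()]
#' @export
compliance <- function(log, gaze, params = fixationParams()) {
    e <- log@entries
    e <- e[!e$inserted & !e$abandoned, , drop = FALSE]
    if (is.null(gaze$valid)) gaze$valid <- TRUE
    validGaze <- gaze[gaze$valid, , drop = FALSE]
    tmin <- min(gaze$t)
    tmax <- max(gaze$t)

    n <- nrow(e)
    valid <- logical(n)
    indeterminate <- logical(n)
    distance <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        t <- e$actualOnset[i]
        if (tmin > t - params$minDuration || tmax < t) {
            indeterminate[i] <- TRUE
            next
        }
        valid[i] <- isFixated(gaze, params, t)
        j <- findInterval(t, validGaze$t)
        if (j >= 1L)
            distance[i] <- sqrt((validGaze$x[j] - params$center[1])^2 +
                                (validGaze$y[j] - params$center[2])^2)
    }

    trials <- data.frame(mediaRef = e$mediaRef,
                         condition = ifelse(e$adapted, "adapted",
                                            "non_adapted"),
                         onset = e$actualOnset, delay = e$delay,
                         valid = ifelse(indeterminate, NA, valid),
                         indeterminate = indeterminate,
                         distance = distance, stringsAsFactors = FALSE)

    summarise <- function(cond) {
        d <- trials[trials$condition == cond, , drop = FALSE]
        det <- d[!d$indeterminate, , drop = FALSE]
        data.frame(condition = cond, nTrials = nrow(det),
                   validFraction = if (nrow(det)) mean(det$valid) else NA,
                   meanDistance = if (nrow(det)) mean(det$distance,
                                                      na.rm = TRUE) else NA,
                   meanDelay = if (nrow(det)) mean(det$delay) else NA,
                   nIndeterminate = sum(d$indeterminate),
                   stringsAsFactors = FALSE)
    }
    summary <- rbind(summarise("adapted"), summarise("non_adapted"))

    adaptedDet <- e$adapted & !indeterminate & !is.na(e$validAtOnset)
    onlineConsistent <- all(valid[adaptedDet] == e$validAtOnset[adaptedDet])
    na <- summary[summary$condition == "non_adapted", , drop = FALSE]
    structure(list(trials = trials, summary = summary,
                   onlineConsistent = onlineConsistent,
                   nonAdaptedValidFraction = na$validFraction),
              class = "complianceReport")
}

#' @export
print.complianceReport <- function(x, ...) {
    cat("Fixation compliance report\n")
    print(x$summary, row.names = FALSE)
    cat(sprintf("online/offline adapted-trial flags consistent: %s\n",
                x$onlineConsistent))
    invisible(x)
}

#' Median split of subjects on fixation performance
#'
#' Splits subjects into High- and Low-Compliant groups on their
#' non-adapted valid-trial fraction: subjects at or above the median are
#' High-Compliant. Operationally the subjects are stably sorted (ties
#' keep input order) and the lower `floor(n/2)` form the Low group, so an
#' odd cohort puts the median subject in the High group — 17 subjects
#' with distinct scores split 9 High / 8 Low.
#'
#' @param x numeric vector of non-adapted valid fractions (one per
#'   subject), or a list of `complianceReport` objects.
#' @return character vector (`"high"`/`"low"`) in input order, named
#'   like `x`.
#' @export
medianSplit <- function(x) {
    if (is.list(x) && !is.numeric(x))
        x <- vapply(x, function(r) r$nonAdaptedValidFraction, numeric(1))
    n <- length(x)
    if (n < 2L) stop("need at least two subjects", call. = FALSE)
    ord <- order(x)                     # stable: ties keep input order
    group <- rep("high", n)
    group[ord[seq_len(n %/% 2L)]] <- "low"
    names(group) <- names(x)
    group
}

#' Time needed to accumulate a fraction of valid trials
#'
#' For each requested fraction `p` and each condition, finds the earliest
#' run time at which the number of valid trials with onset at or before
#' that time reaches `ceiling(p * N)`, where `N` counts the condition's
#' determinate trials. Fractions a condition never reaches are flagged,
#' not extrapolated. The resulting curve is nondecreasing in `p`.
#'
#' @param trials a `complianceReport` (its `trials` table is used), or a
#'   data.frame with columns `condition`, `onset` (ms) and `valid`.
#' @param fractions target fractions in `(0, 1]`.
#' @return data.frame with columns `condition`, `fraction`, `time` (ms,
#'   `NA` when unreached) and `reached`.
#' @export
timeToValid <- function(trials, fractions = c(0.5, 0.7, 0.9, 0.95, 1)) {
    if (inherits(trials, "complianceReport")) trials <- trials$trials
    stopifnot(all(fractions > 0), all(fractions <= 1))
    if (!is.null(trials$indeterminate))
        trials <- trials[!trials$indeterminate, , drop = FALSE]
    out <- lapply(split(trials, trials$condition), function(d) {
        N <- nrow(d)
        d <- d[order(d$onset), , drop = FALSE]
        validOnsets <- d$onset[d$valid]
        k <- ceiling(fractions * N)
        reached <- k <= length(validOnsets)
        time <- rep(NA_real_, length(k))
        time[reached] <- validOnsets[k[reached]]
        data.frame(condition = d$condition[1L], fraction = fractions,
                   time = time, reached = reached,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
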