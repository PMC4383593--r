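## Gaze handling. A gaze stream is a data.frame with columns t (ms),
## x, y (degrees of visual angle, screen-centre origin) and valid
## (pupil/corneal reflex found). Thresholds are applied in time units, so
## the code is sampling-rate agnostic.

#' Fixation-identification parameters
#'
#' Parameters of dispersion-threshold identification (I-DT) and of the
#' centre-fixation acceptance criterion: a window of at least
#' `minDuration` whose dispersion — the Salvucci–Goldberg metric
#' (max x - min x) + (max y - min y) — stays within
#' `dispersionThreshold`, with a centroid within `centerRadius` of the
#' screen centre. Defaults: 200 ms, 1 degree, 2 degrees.
#'
#' @param minDuration minimum fixation duration (ms).
#' @param dispersionThreshold maximum dispersion (degrees).
#' @param centerRadius maximum centroid eccentricity for a fixation to
#'   count as centre-directed (degrees).
#' @param center screen-centre coordinates (degrees), default `c(0, 0)`.
#' @return list of class `fixationParams`.
#' @export
fixationParams <- function(minDuration = 200, dispersionThreshold = 1,
                           centerRadius = 2, center = c(0, 0)) {
    stopifnot(minDuration > 0, dispersionThreshold > 0, centerRadius > 0)
    structure(list(minDuration = minDuration,
                   dispersionThreshold = dispersionThreshold,
                   centerRadius = centerRadius, center = center),
              class = "fixationParams")
}

.dispersion <- function(x, y) {
    (max(x) - min(x)) + (max(y) - min(y))
}

#' Identify fixations by dispersion-threshold (I-DT)
#'
#' Classic I-DT segmentation: starting from the earliest unconsumed
#' sample, a window is grown until it spans at least `minDuration`; if its
#' dispersion is within threshold the window keeps expanding sample by
#' sample until dispersion would be exceeded, and a fixation is emitted
#' with the window's centroid; otherwise the window slides forward by one
#' sample. Invalid (dropout) samples break windows: fixations never span
#' them. Emitted fixations are disjoint and time-ordered.
#'
#' @param stream gaze stream data.frame (`t`, `x`, `y`, `valid`),
#'   time-sorted; a missing `valid` column is taken as all-valid.
#' @param params a [fixationParams()].
#' @return data.frame with columns `tStart`, `tEnd`, `centroidX`,
#'   `centroidY`, `dispersion`; zero rows for an empty stream.
#' @examples
#' s <- data.frame(t = seq(0, 1000, by = 20), x = 0.2, y = -0.1,
#'                 valid = TRUE)
#' idtFixations(s, fixationParams())
#' @export
idtFixations <- function(stream, params = fixationParams()) {
    empty <- data.frame(tStart = numeric(), tEnd = numeric(),
                        centroidX = numeric(), centroidY = numeric(),
                        dispersion = numeric())
    if (!nrow(stream)) return(empty)
    if (is.null(stream$valid)) stream$valid <- TRUE
    if (is.unsorted(stream$t))
        stop("gaze stream must be time-sorted", call. = FALSE)

    ## segment at invalid samples
    runs <- rle(stream$valid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    out <- list()
    for (s in which(runs$values)) {
        seg <- stream[starts[s]:ends[s], , drop = FALSE]
        out[[length(out) + 1L]] <- .idtSegment(seg, params)
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.idtSegment <- function(seg, params) {
    ts <- seg$t; xs <- seg$x; ys <- seg$y
    n <- length(ts)
    res <- list()
    i <- 1L
    while (i <= n) {
        j <- i
        while (j <= n && ts[j] - ts[i] < params$minDuration) j <- j + 1L
        if (j > n) break
        if (.dispersion(xs[i:j], ys[i:j]) <= params$dispersionThreshold) {
            while (j < n &&
                   .dispersion(xs[i:(j + 1L)], ys[i:(j + 1L)]) <=
                   params$dispersionThreshold)
                j <- j + 1L
            res[[length(res) + 1L]] <- data.frame(
                tStart = ts[i], tEnd = ts[j],
                centroidX = mean(xs[i:j]), centroidY = mean(ys[i:j]),
                dispersion = .dispersion(xs[i:j], ys[i:j]))
            i <- j + 1L
        } else {
            i <- i + 1L
        }
    }
    if (!length(res))
        return(data.frame(tStart = numeric(), tEnd = numeric(),
                          centroidX = numeric(), centroidY = numeric(),
                          dispersion = numeric()))
    do.call(rbind, res)
}

#' Real-time centre-fixation test
#'
#' Decides whether the subject is fixating the screen centre at time `t`,
#' using the trailing window of exactly `minDuration` ending at `t`: true
#' iff the stream covers the window, every sample inside it is valid, the
#' window dispersion is within threshold, and the window centroid lies
#' within `centerRadius` of the screen centre. If the stream does not
#' reach back to `t - minDuration` the fixation cannot be confirmed and
#' the result is `FALSE`.
#'
#' @param stream gaze stream data.frame (`t`, `x`, `y`, `valid`),
#'   time-sorted.
#' @param params a [fixationParams()].
#' @param t query time (ms).
#' @return logical scalar.
#' @export
isFixated <- function(stream, params, t) {
    if (!nrow(stream)) return(FALSE)
    ts <- stream$t
    if (ts[1L] > t - params$minDuration || t < ts[1L]) return(FALSE)
    lo <- findInterval(t - params$minDuration, ts) # last sample <= t-minDur
    hi <- findInterval(t, ts)
    if (hi < lo) return(FALSE)
    w <- seq.int(lo, hi)   # window [last sample <= t - minDur, ..., t]
    valid <- stream$valid
    if (is.null(valid)) valid <- rep(TRUE, length(ts))
    if (!all(valid[w])) return(FALSE)
    x <- stream$x[w]; y <- stream$y[w]
    if (.dispersion(x, y) > params$dispersionThreshold) return(FALSE)
    cx <- mean(x) - params$center[1L]
    cy <- mean(y) - params$center[2L]
    sqrt(cx * cx + cy * cy) <= params$centerRadius
}

#' Gaze system-variable provider
#'
#' Wraps a gaze stream as a provider serving the system variables
#' `eyePosIsFixated` (via [isFixated()]), `eyePosX` and `eyePosY` (the
#' latest valid sample's coordinates at or before the query time).
#' Register the returned function in the provider list passed to
#' [runClosedLoop()], keyed by the source identifier the experiment
#' declares.
#'
#' @param stream gaze stream data.frame (`t`, `x`, `y`, `valid`).
#' @param params a [fixationParams()].
#' @return `function(varName, t)`; unknown variable names raise an error
#'   naming the variable.
#' @export
gazeProvider <- function(stream, params = fixationParams()) {
    if (is.null(stream$valid)) stream$valid <- TRUE
    validStream <- stream[stream$valid, , drop = FALSE]
    function(varName, t) {
        switch(varName,
            eyePosIsFixated = isFixated(stream, params, t),
            eyePosX = ,
            eyePosY = {
                i <- findInterval(t, validStream$t)
                if (i < 1L) return(NA_real_)
                if (varName == "eyePosX") validStream$x[i]
                else validStream$y[i]
            },
            stop(sprintf("gaze provider does not serve variable '%s'",
                         varName), call. = FALSE))
    }
}

#' Read and write gaze streams as tab-separated text
#'
#' Columns: `t_ms`, `x_deg`, `y_deg`, `valid`.
#'
#' @param stream gaze stream data.frame.
#' @param path TSV file path.
#' @return `writeGazeStream()` returns `path` invisibly;
#'   `readGazeStream()` returns the stream data.frame.
#' @export
writeGazeStream <- function(stream, path) {
    out <- data.frame(t_ms = stream$t, x_deg = stream$x,
                      y_deg = stream$y, valid = stream$valid)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGazeStream
#' @export
readGazeStream <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    data.frame(t = d$t_ms, x = d$x_deg, y = d$y_deg,
               valid = as.logical(d$valid))
}

#' Convert a pixel gaze stream to degrees of visual angle
#'
#' Calibration helper for trackers reporting screen pixels: converts
#' pixel offsets from the screen centre to degrees given the physical
#' screen geometry and viewing distance.
#'
#' @param stream data.frame with `t`, `x`, `y` in pixels (centre origin)
#'   and `valid`.
#' @param screenWidthPx,screenWidthCm horizontal resolution and physical
#'   width of the display.
#' @param distanceCm eye-to-screen viewing distance.
#' @return The stream with `x`, `y` in degrees.
#' @export
pixelsToDegrees <- function(stream, screenWidthPx, screenWidthCm,
                            distanceCm) {
    cmPerPx <- screenWidthCm / screenWidthPx
    toDeg <- function(px) atan2(px * cmPerPx, distanceCm) * 180 / pi
    stream$x <- toDeg(stream$x)
    stream$y <- toDeg(stream$y)
    stream
}
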