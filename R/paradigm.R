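## 2x2 picture paradigm (negative/neutral x adapted/non-adapted): every
## picture appears twice, once per adaptation condition, in an intermixed
## pseudo-random order; which condition comes first is chosen by a
## valence-matching randomization search.

#' Synthetic picture rating table
#'
#' Emulates a normed affective picture set: valence and arousal ratings
#' on the 1-10 scale for a negative and a neutral picture class. Default
#' ranges place negative pictures at low valence / high arousal and
#' neutral pictures mid-scale, drawn uniformly.
#'
#' @param nNegative,nNeutral pictures per class.
#' @param seed optional RNG seed.
#' @param valenceNegative,valenceNeutral,arousalNegative,arousalNeutral
#'   length-2 ranges (rating points in `[1, 10]`) sampled uniformly.
#' @return data.frame with columns `pictureId`, `valence`, `arousal`,
#'   `emotionClass` (`"negative"`/`"neutral"`).
#' @export
syntheticRatings <- function(nNegative = 60, nNeutral = 60, seed = NULL,
                             valenceNegative = c(1.5, 4),
                             valenceNeutral = c(4, 6.5),
                             arousalNegative = c(5, 9),
                             arousalNeutral = c(2, 5)) {
    if (!is.null(seed)) set.seed(seed)
    data.frame(
        pictureId = c(sprintf("neg%03d", seq_len(nNegative)),
                      sprintf("neut%03d", seq_len(nNeutral))),
        valence = c(runif(nNegative, valenceNegative[1], valenceNegative[2]),
                    runif(nNeutral, valenceNeutral[1], valenceNeutral[2])),
        arousal = c(runif(nNegative, arousalNegative[1], arousalNegative[2]),
                    runif(nNeutral, arousalNeutral[1], arousalNeutral[2])),
        emotionClass = rep(c("negative", "neutral"),
                           c(nNegative, nNeutral)),
        stringsAsFactors = FALSE)
}

.checkRatings <- function(ratings) {
    stopifnot(is.data.frame(ratings))
    if (!nrow(ratings)) stop("empty rating table", call. = FALSE)
    need <- c("pictureId", "valence", "arousal", "emotionClass")
    miss <- setdiff(need, colnames(ratings))
    if (length(miss))
        stop("rating table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (any(ratings$valence < 1 | ratings$valence > 10) ||
        any(ratings$arousal < 1 | ratings$arousal > 10))
        stop("ratings must lie in [1, 10]", call. = FALSE)
    invisible(ratings)
}

#' Select a valence-matched first-presentation randomization
#'
#' Every picture is shown twice, once adapted and once non-adapted; the
#' free choice is which condition comes first. `nCandidates` random
#' divisions of each class into first-shown-adapted vs
#' first-shown-non-adapted halves are generated, each is scored by the
#' absolute difference in mean valence between the two halves of the
#' negative class (the first reaction to a negative picture is the
#' sensitive quantity), and the argmin is returned; ties break to the
#' earliest candidate.
#'
#' @param ratings rating table (see [syntheticRatings()]); needs at least
#'   two pictures per class.
#' @param nCandidates number of random divisions scored (default 1000).
#' @param seed optional RNG seed.
#' @return list with elements `randomization` (data.frame `pictureId`,
#'   `firstCondition`), `scores` (all candidate scores), and
#'   `diagnostics`: `selectedIndex`, `meanDiff` (the achieved minimum),
#'   `sdAcrossCandidates` (spread of the candidate scores) and
#'   `sdDiffSelected` (difference in valence spread between the selected
#'   halves).
#' @export
selectRandomization <- function(ratings, nCandidates = 1000, seed = NULL) {
    .checkRatings(ratings)
    if (!is.null(seed)) set.seed(seed)
    classes <- split(seq_len(nrow(ratings)), ratings$emotionClass)
    if (any(lengths(classes) < 2L))
        stop("need at least two pictures per class", call. = FALSE)
    negIdx <- classes[["negative"]]
    valNeg <- ratings$valence[negIdx]

    assignments <- vector("list", nCandidates)
    scores <- numeric(nCandidates)
    for (k in seq_len(nCandidates)) {
        firstAdapted <- logical(nrow(ratings))
        for (cl in classes) {
            half <- sample(cl, length(cl) %/% 2L)
            firstAdapted[half] <- TRUE
        }
        a <- firstAdapted[negIdx]
        scores[k] <- abs(mean(valNeg[a]) - mean(valNeg[!a]))
        assignments[[k]] <- firstAdapted
    }
    sel <- which.min(scores)
    fa <- assignments[[sel]]
    aNeg <- fa[negIdx]
    list(randomization = data.frame(
             pictureId = ratings$pictureId,
             firstCondition = ifelse(fa, "adapted", "non_adapted"),
             stringsAsFactors = FALSE),
         scores = scores,
         diagnostics = list(selectedIndex = sel, meanDiff = scores[sel],
             sdAcrossCandidates = sd(scores),
             sdDiffSelected = abs(sd(valNeg[aNeg]) - sd(valNeg[!aNeg]))))
}

#' Generate an adaptive 2x2 picture experiment
#'
#' Builds a complete [ExperimentSpec-class] for the gaze-contingent
#' picture paradigm: every picture is scheduled twice (once adapted, once
#' non-adapted) in an intermixed pseudo-random order with
#' first-presentation conditions chosen by [selectRandomization()].
#' Pictures last `pictureDuration` ms; consecutive inter-trial intervals
#' are drawn from `itiSet`. Adapted presentations carry a
#' centre-fixation constraint whose else-action inserts a short fixation
#' cross and shifts all following events; each (class, condition) cell
#' maps to its own dynamic regressor through a shared impulse transfer
#' function.
#'
#' @param ratings rating table, see [syntheticRatings()].
#' @param itiSet inter-trial intervals (ms) sampled uniformly; defaults
#'   to four equally spaced values spanning 4-6.25 s.
#' @param pictureDuration picture presentation time (ms), default 500.
#' @param fillerDuration duration of the inserted fixation-cross filler
#'   (ms), default 8 — this also sets the constraint polling cadence.
#' @param startOffset onset of the first trial (ms).
#' @param tr repetition time (ms).
#' @param ignoreScansAtStart leading scans discarded before the GLM.
#' @param nCandidates randomization candidates scored.
#' @param seed optional RNG seed; the same seed reproduces the schedule.
#' @param gazeSource source identifier the gaze provider must register
#'   under.
#' @return An [ExperimentSpec-class] that [validateRules()] accepts.
#' @examples
#' spec <- generateSchedule(syntheticRatings(2, 2, seed = 1), seed = 1)
#' timetable(spec)
#' @export
generateSchedule <- function(ratings, itiSet = c(4000, 4750, 5500, 6250),
                             pictureDuration = 500, fillerDuration = 8,
                             startOffset = 10000, tr = 2000,
                             ignoreScansAtStart = 20L, nCandidates = 1000,
                             seed = NULL,
                             gazeSource = "org.flexstim.gaze") {
    .checkRatings(ratings)
    stopifnot(all(itiSet >= 0))
    if (!is.null(seed)) set.seed(seed)
    classes <- split(seq_len(nrow(ratings)), ratings$emotionClass)
    first <- if (all(lengths(classes) >= 2L)) {
        selectRandomization(ratings, nCandidates)$randomization$firstCondition
    } else {
        ## too few pictures for valence matching: random first condition
        sample(c("adapted", "non_adapted"), nrow(ratings), replace = TRUE)
    }

    n <- nrow(ratings)
    slotPic <- sample(rep(seq_len(n), 2L))
    condition <- character(2L * n)
    seen <- logical(n)
    for (s in seq_along(slotPic)) {
        p <- slotPic[s]
        condition[s] <- if (!seen[p]) first[p]
                        else if (first[p] == "adapted") "non_adapted"
                        else "adapted"
        seen[p] <- TRUE
    }

    regOf <- function(class, cond)
        paste0("REG_", ifelse(class == "negative", "NEG", "NEUT"),
               ifelse(cond == "adapted", "_AD", "_NA"))
    moId <- paste0(ratings$pictureId[slotPic],
                   ifelse(condition == "adapted", "_ad", "_na"))

    iti <- sample(itiSet, 2L * n, replace = TRUE)
    onset <- startOffset + c(0, cumsum(pictureDuration + iti[-1L]))
    timetable <- data.frame(onset = onset, duration = pictureDuration,
                            mediaRef = moId, stringsAsFactors = FALSE)

    pictureMedia <- data.frame(
        id = moId, name = ratings$pictureId[slotPic], kind = "image",
        contentRef = paste0("pics/", ratings$pictureId[slotPic], ".jpg"),
        posX = 0, posY = 0,
        constraintRef = ifelse(condition == "adapted", "co1",
                               NA_character_),
        regressorRef = regOf(ratings$emotionClass[slotPic], condition),
        transferFunctionRef = "tranF1", stringsAsFactors = FALSE)
    fixcross <- data.frame(id = "FIXCROSS", name = "fixation cross",
        kind = "text", contentRef = "+", posX = 0, posY = 0,
        constraintRef = NA_character_, regressorRef = NA_character_,
        transferFunctionRef = NA_character_, stringsAsFactors = FALSE)

    plannedEnd <- max(onset) + pictureDuration
    maxLength <- plannedEnd + 600000  # slack for adaptation delays
    regIds <- c("REG_NEG_AD", "REG_NEG_NA", "REG_NEUT_AD", "REG_NEUT_NA")
    regressorSpecs <- data.frame(id = regIds,
        name = c("negative adapted", "negative non-adapted",
                 "neutral adapted", "neutral non-adapted"),
        maxLength = maxLength, refFct = "gloverKernel",
        firstDerivative = FALSE, secondDerivative = FALSE,
        zeroMean = FALSE, stringsAsFactors = FALSE)

    experimentSpec(
        media = rbind(fixcross, pictureMedia),
        timetable = timetable,
        systemVariables = data.frame(source = gazeSource, id = "sV1",
                                     name = "eyePosIsFixated",
                                     stringsAsFactors = FALSE),
        constraints = list(co1 = newConstraint("co1", "sV1",
            actionsElse = list(insertEventAction(fillerDuration,
                                                 "FIXCROSS", TRUE)))),
        transferFunctions = data.frame(id = "tranF1", timeOffset = 0,
                                       durationScale = 0,
                                       parametricScale = 1,
                                       stringsAsFactors = FALSE),
        regressorSpecs = regressorSpecs,
        ignoreScansAtStart = ignoreScansAtStart, tr = tr)
}
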