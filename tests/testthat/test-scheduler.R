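svTable <- function(n = 1) {
    data.frame(source = "org.example.tracker",
               id = paste0("sV", seq_len(n)),
               name = paste0("flag", seq_len(n)),
               stringsAsFactors = FALSE)
}

test_that("constraint evaluation is the conjunction of its conditions", {
    sys <- svTable(3)
    co <- newConstraint("c", sys$id,
                        actionsThen = list(adaptParamsAction(1, 1)),
                        actionsElse = list(insertEventAction(8, "F")))

    # exhaustive truth table vs. brute-force conjunction
    for (bits in 0:7) {
        vals <- as.logical(bitwAnd(bits, c(1, 2, 4)))
        names(vals) <- sys$name
        prov <- list(org.example.tracker = function(v, t) vals[[v]])
        res <- evaluateConstraint(co, prov, 0, sys)
        expect_identical(res$result, all(vals))
        expect_identical(res$actions,
                         if (all(vals)) co$actionsThen else co$actionsElse)
    }
})

test_that("the empty conjunction is true and missing providers are named", {
    sys <- svTable(1)
    co <- newConstraint("c", character(),
                        actionsThen = list(adaptParamsAction(0, 0)))
    res <- evaluateConstraint(co, list(), 0, sys)
    expect_true(res$result)
    expect_identical(res$actions, co$actionsThen)

    needs <- newConstraint("c", "sV1")
    expect_error(evaluateConstraint(needs, list(), 0, sys),
                 "org.example.tracker")
})

test_that("insert-and-shift moves exactly the events at or after the insertion", {
    tt <- data.frame(onset = c(100, 200, 300), duration = 10,
                     mediaRef = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
    out <- insertAndShift(tt, 200, insertEventAction(8, "F", TRUE))
    expect_identical(out$onset, c(100, 200, 208, 308))
    expect_identical(out$mediaRef, c("a", "F", "b", "c"))
    # pairwise gaps among shifted events unchanged
    expect_identical(diff(out$onset[3:4]), diff(tt$onset[2:3]))

    noShift <- insertAndShift(tt, 200, insertEventAction(8, "F", FALSE))
    expect_identical(noShift$onset[noShift$mediaRef != "F"], tt$onset)
})

test_that("repeated insertions match a from-scratch replay of the schedule", {
    tt <- data.frame(onset = seq(1000, 5000, by = 1000), duration = 100,
                     mediaRef = letters[1:5], stringsAsFactors = FALSE)
    k <- 7
    cur <- tt
    at <- 1000
    for (i in seq_len(k)) {
        cur <- insertAndShift(cur, at, insertEventAction(8, "F", TRUE))
        at <- at + 8
    }
    # replay oracle: rebuild from the original schedule in one pass
    replay <- tt
    replay$onset <- replay$onset + ifelse(tt$onset >= 1000, 8 * k, 0)
    fillers <- data.frame(onset = 1000 + 8 * (seq_len(k) - 1), duration = 8,
                          mediaRef = "F", stringsAsFactors = FALSE)
    expected <- rbind(replay, fillers)
    expected <- expected[order(expected$onset), ]
    rownames(expected) <- NULL
    expect_equal(cur, expected)
})

test_that("replace and reposition actions touch only what they should", {
    tt <- data.frame(onset = c(0, 100), duration = 10,
                     mediaRef = c("a", "b"), stringsAsFactors = FALSE)
    m <- data.frame(id = c("a", "b", "n"), posX = c(5, 0, 0),
                    posY = c(-5, 0, 0))

    rep1 <- applyAction(tt, 1, replaceStimulusAction("n"), m)
    expect_identical(rep1$mediaRef, c("n", "b"))
    expect_identical(rep1$onset, tt$onset)
    expect_identical(rep1$duration, tt$duration)

    expect_error(applyAction(tt, 1, replaceStimulusAction("zz"), m), "zz")

    same <- applyAction(tt, 1, replaceStimulusAction("a"), m)
    expect_identical(same, tt)

    moved <- applyAction(tt, 2, adaptParamsAction(3.5, -1), m)
    expect_identical(moved$posX[2], 3.5)
    expect_identical(moved$posY[2], -1)
    expect_identical(moved$mediaRef, tt$mediaRef)

    nudged <- applyAction(tt, 1, adaptParamsAction(1, 1, absolute = FALSE),
                          m)
    expect_identical(nudged$posX[1], 6)  # relative to the media default
    expect_identical(nudged$posY[1], -4)
})

test_that("a fully compliant subject is presented exactly as planned", {
    run <- smallAdaptiveRun(nPerClass = 3, complianceLevel = 1, seed = 4)
    e <- entries(run$log)
    expect_false(any(e$inserted))
    expect_identical(e$actualOnset, e$plannedOnset)
    expect_true(all(e$delay == 0))
    expect_true(all(e$validAtOnset[e$adapted]))
})

test_that("waiting is realized as 8-ms fillers until the constraint holds", {
    spec <- generateSchedule(syntheticRatings(1, 1, seed = 3), seed = 3,
                             nCandidates = 10)
    tt <- timetable(spec)
    constrained <- !is.na(media(spec)$constraintRef[
        match(tt$mediaRef, media(spec)$id)])
    firstAdapted <- tt$onset[which(constrained)[1]]
    # provider refuses until 400 ms past the planned onset of the first
    # adapted trial, then accepts everything
    prov <- booleanProvider(function(t) t >= firstAdapted + 400)
    log <- runClosedLoop(spec, list(org.flexstim.gaze = prov))
    e <- entries(log)
    first <- e[e$adapted & e$plannedOnset == firstAdapted, ]
    expect_identical(first$delay, 400)
    expect_identical(first$nInsertions, 50L)
    expect_true(first$validAtOnset)
    # delay always equals insertions x filler duration
    expect_identical(e$delay[e$adapted], 8 * as.numeric(e$nInsertions[e$adapted]))
})

test_that("shift conservation and order preservation hold on adaptive runs", {
    run <- smallAdaptiveRun(nPerClass = 4, complianceLevel = 0.5, seed = 9)
    e <- entries(run$log)
    tt <- timetable(run$spec)
    plannedEnd <- max(tt$onset + tt$duration)
    expect_identical(runEnd(run$log) - plannedEnd,
                     sum(e$duration[e$inserted]))
    # original timetable order is a subsequence of the log
    mainRows <- e[!e$inserted, ]
    expect_identical(mainRows$mediaRef, tt$mediaRef)
    # gating soundness: adapted events only shown while the constraint held
    expect_true(all(mainRows$validAtOnset[mainRows$adapted]))
    # presented onsets strictly increasing
    shown <- e[!e$abandoned & e$duration > 0, ]
    expect_true(all(diff(shown$actualOnset) > 0))
})

test_that("identical spec and provider seed give identical logs", {
    a <- smallAdaptiveRun(nPerClass = 3, complianceLevel = 0.6, seed = 11)
    b <- smallAdaptiveRun(nPerClass = 3, complianceLevel = 0.6, seed = 11)
    expect_identical(entries(a$log), entries(b$log))
    expect_identical(runEnd(a$log), runEnd(b$log))
})

test_that("a never-satisfied constraint is abandoned at the stop time", {
    spec <- generateSchedule(syntheticRatings(1, 1, seed = 5), seed = 5,
                             nCandidates = 10)
    prov <- booleanProvider(function(t) FALSE)
    stopAt <- max(timetable(spec)$onset) + 2000
    log <- runClosedLoop(spec, list(org.flexstim.gaze = prov),
                         stop = stopAt)
    e <- entries(log)
    expect_true(any(e$abandoned[e$adapted]))
    expect_true(all(is.na(e$validAtOnset[e$abandoned])))
    # nothing is presented after the stop time (fillers may shift later
    # events past it, in which case they are abandoned, not shown)
    expect_true(all(e$actualOnset[!e$abandoned] <= stopAt))
    expect_true(all(e$actualOnset[e$inserted] <= stopAt))
})

test_that("event logs survive the BIDS-style TSV round trip", {
    run <- smallAdaptiveRun(nPerClass = 2, complianceLevel = 0.7, seed = 13)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeEventLog(run$log, path)
    back <- readEventLog(path)
    expect_equal(entries(back), entries(run$log), tolerance = 1e-9)
    expect_equal(runEnd(back), runEnd(run$log))
})
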