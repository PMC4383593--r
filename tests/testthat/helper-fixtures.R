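# Fixtures are built in code. The adaptive example document below is the
# canonical gaze-contingent configuration: a constraint on the
# eye-tracker's fixation flag whose else-branch inserts an 8-ms fixation
# cross and shifts everything that follows, a constrained picture mapped
# onto a dynamic regressor through an impulse transfer function, and two
# dynamic regressors on a 4000-s run. Attribute whitespace is
# deliberately sloppy (spaces around '=') to exercise tolerance.

adaptiveExampleXml <- function() {
'<experiment>
  <constraints>
    <systemVariables>
      <systemVariable source = "de.mpg.de.ASLEyetracker" systemVariableID = "sV1" systemVariableName = "eyePosIsFixated"/>
      <systemVariable source = "de.mpg.de.ASLEyetracker" systemVariableID = "sV2" systemVariableName = "eyePosX"/>
      <systemVariable source = "de.mpg.de.ASLEyetracker" systemVariableID = "sV3" systemVariableName = "eyePosY"/>
    </systemVariables>
    <constraint constraintID = "co1">
      <conditions>
        <condition systemVariableRef = "sV1"/>
      </conditions>
      <stimulusActions_else>
        <stimulusAction>
          <insertNewStimulusEvent duration = "8" mediaObjectRef = "FIXCROSS" shiftFollowingStimulusEvents = "true"/>
        </stimulusAction>
      </stimulusActions_else>
    </constraint>
  </constraints>
  <mediaObjects>
    <mediaObject moID = "FIXCROSS" name = "fixation cross" type = "TEXT">
      <contentText><text>+</text><posX>0</posX><posY>0</posY></contentText>
    </mediaObject>
    <mediaObject moID = "PicID1" name = "1019" type = "IMAGE" useConstraint = "co1">
      <contentImage>
        <imageFile>pics/1019.jpg</imageFile>
        <posX>0</posX>
        <posY>0</posY>
      </contentImage>
      <regressorAssignment assignToRegressor = "REG_NEGDYN" useTransferFunction = "tranF1"/>
    </mediaObject>
    <mediaObject moID = "PicID2" name = "7010" type = "IMAGE">
      <contentImage>
        <imageFile>pics/7010.jpg</imageFile>
        <posX>0</posX>
        <posY>0</posY>
      </contentImage>
      <regressorAssignment assignToRegressor = "REG_NEUTDYN" useTransferFunction = "tranF1"/>
    </mediaObject>
  </mediaObjects>
  <timeTable>
    <stimEvent onset = "4000" duration = "500" mediaObjectRef = "PicID1"/>
    <stimEvent onset = "9000" duration = "500" mediaObjectRef = "PicID2"/>
  </timeTable>
  <transferFunctions>
    <transferFunction transferFunctionID = "tranF1" timeOffset = "0" durationScaleFactor = "0" parametricScaleFactor = "1"/>
  </transferFunctions>
  <paradigm ignoreScansAtStart = "20" tr = "2000">
    <dynamicDesignStruct maxLength = "4000000">
      <dynamicTimeBasedRegressor length = "4000000" name = "neg_dynamic" regressorID = "REG_NEGDYN" scaleHeightToZeroMean = "false" useRefFct = "gloverKernel" useRefFctFirstDerivative = "false" useRefFctSecondDerivative = "false"/>
      <dynamicTimeBasedRegressor length = "4000000" name = "neut_dynamic" regressorID = "REG_NEUTDYN" scaleHeightToZeroMean = "false" useRefFct = "gloverKernel" useRefFctFirstDerivative = "false" useRefFctSecondDerivative = "false"/>
    </dynamicDesignStruct>
  </paradigm>
</experiment>'
}

# constant-rate gaze stream helper
makeStream <- function(t, x, y, valid = TRUE) {
    data.frame(t = t, x = rep_len(x, length(t)), y = rep_len(y, length(t)),
               valid = rep_len(valid, length(t)))
}

# O(n^2) brute-force I-DT oracle: greedy left-to-right selection of
# maximal low-dispersion windows spanning at least minDuration, with
# dispersion computed directly on every candidate slice. Invalid samples
# split the stream.
bruteForceFixations <- function(stream, params) {
    disp <- function(i, j, s)
        (max(s$x[i:j]) - min(s$x[i:j])) + (max(s$y[i:j]) - min(s$y[i:j]))
    segs <- split(stream, cumsum(!stream$valid))
    res <- list()
    for (seg in segs) {
        seg <- seg[seg$valid, , drop = FALSE]
        n <- nrow(seg)
        i <- 1L
        while (i <= n) {
            jmax <- NA_integer_
            for (j in seq.int(i, n)) {
                if (disp(i, j, seg) > params$dispersionThreshold) break
                jmax <- j
            }
            ok <- !is.na(jmax) &&
                seg$t[jmax] - seg$t[i] >= params$minDuration
            if (ok) {
                res[[length(res) + 1L]] <- data.frame(
                    tStart = seg$t[i], tEnd = seg$t[jmax],
                    centroidX = mean(seg$x[i:jmax]),
                    centroidY = mean(seg$y[i:jmax]),
                    dispersion = disp(i, jmax, seg))
                i <- jmax + 1L
            } else {
                i <- i + 1L
            }
        }
    }
    if (!length(res))
        return(data.frame(tStart = numeric(), tEnd = numeric(),
                          centroidX = numeric(), centroidY = numeric(),
                          dispersion = numeric()))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

# random but valid experiment specifications for round-trip properties
makeRandomSpec <- function(seed) {
    set.seed(seed)
    nMedia <- sample(1:5, 1)
    kinds <- sample(c("image", "text", "audio"), nMedia, replace = TRUE)
    nReg <- sample(0:2, 1)
    regIds <- if (nReg) paste0("R", seq_len(nReg)) else character()
    tfs <- data.frame(id = "tf1", timeOffset = sample(0:200, 1),
                      durationScale = sample(c(0, 1), 1),
                      parametricScale = round(runif(1, 0.5, 2), 3),
                      stringsAsFactors = FALSE)
    media <- data.frame(
        id = paste0("m", seq_len(nMedia)),
        name = paste0("media ", seq_len(nMedia)), kind = kinds,
        contentRef = paste0("content/", seq_len(nMedia)),
        posX = sample(-100:100, nMedia, replace = TRUE),
        posY = sample(-100:100, nMedia, replace = TRUE),
        constraintRef = NA_character_,
        regressorRef = if (nReg) sample(c(regIds, NA), nMedia,
                                        replace = TRUE) else NA_character_,
        transferFunctionRef = NA_character_, stringsAsFactors = FALSE)
    media$transferFunctionRef[!is.na(media$regressorRef)] <- "tf1"
    useCo <- sample(c(TRUE, FALSE), 1)
    cons <- list()
    sysv <- data.frame(source = character(), id = character(),
                       name = character(), stringsAsFactors = FALSE)
    if (useCo) {
        sysv <- data.frame(source = "org.example.tracker", id = "sV1",
                           name = "eyePosIsFixated",
                           stringsAsFactors = FALSE)
        cons <- list(c1 = newConstraint("c1", "sV1",
            actionsThen = list(adaptParamsAction(10, -5)),
            actionsElse = list(insertEventAction(8, media$id[1]),
                               replaceStimulusAction(media$id[1]))))
        media$constraintRef[nMedia] <- "c1"
    }
    nEv <- sample(0:6, 1)
    timetable <- data.frame(
        onset = sort(sample(0:50000, nEv)),
        duration = sample(c(0, 500, 1000), nEv, replace = TRUE),
        mediaRef = sample(media$id, nEv, replace = TRUE),
        stringsAsFactors = FALSE)
    regs <- if (nReg) data.frame(id = regIds, name = paste0("reg ", regIds),
        maxLength = 600000, refFct = "gloverKernel",
        firstDerivative = sample(c(TRUE, FALSE), nReg, replace = TRUE),
        secondDerivative = FALSE,
        zeroMean = sample(c(TRUE, FALSE), nReg, replace = TRUE),
        stringsAsFactors = FALSE)
    else flexstim:::.emptyRegressorSpecs()
    experimentSpec(media = media, timetable = timetable,
                   systemVariables = sysv, constraints = cons,
                   transferFunctions = if (nReg || useCo) tfs else
                       flexstim:::.emptyTransferFunctions(),
                   regressorSpecs = regs,
                   ignoreScansAtStart = sample(0:20, 1),
                   tr = sample(c(1000, 2000, 2500), 1))
}

specsEqual <- function(a, b) {
    for (nm in methods::slotNames(a)) {
        if (!isTRUE(all.equal(methods::slot(a, nm), methods::slot(b, nm))))
            return(nm)
    }
    TRUE
}

# boolean provider factory keyed by a schedule of truth times
booleanProvider <- function(fn) {
    function(varName, t) {
        stopifnot(varName == "eyePosIsFixated")
        fn(t)
    }
}

# small adaptive paradigm + simulated subject, for closed-loop tests
smallAdaptiveRun <- function(nPerClass = 4, complianceLevel = 0.5,
                             seed = 1) {
    spec <- generateSchedule(syntheticRatings(nPerClass, nPerClass,
                                              seed = seed),
                             seed = seed, nCandidates = 50)
    plannedEnd <- max(timetable(spec)$onset + timetable(spec)$duration)
    gaze <- simulateGaze(gazeModel(compliance = complianceLevel),
                         duration = plannedEnd + 60000 +
                             2000 * nPerClass * 4,
                         seed = seed + 1000)
    log <- runClosedLoop(spec,
                         list(org.flexstim.gaze = gazeProvider(gaze)),
                         stop = max(gaze$t))
    list(spec = spec, gaze = gaze, log = log)
}
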