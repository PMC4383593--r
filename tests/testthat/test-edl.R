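test_that("the adaptive example document parses into linked constructs", {
    spec <- parseExperiment(adaptiveExampleXml())

    co <- constraints(spec)[["co1"]]
    expect_identical(co$conditions, "sV1")
    expect_length(co$actionsElse, 1L)
    act <- co$actionsElse[[1L]]
    expect_identical(act$type, "insertEvent")
    expect_identical(act$duration, 8)
    expect_identical(act$mediaRef, "FIXCROSS")
    expect_true(act$shiftFollowing)

    m <- media(spec)
    pic <- m[m$id == "PicID1", ]
    expect_identical(pic$constraintRef, "co1")
    expect_identical(pic$regressorRef, "REG_NEGDYN")
    expect_identical(pic$transferFunctionRef, "tranF1")
    tf <- transferFunctions(spec)
    expect_identical(tf$timeOffset[tf$id == "tranF1"], 0)
    expect_identical(tf$durationScale[tf$id == "tranF1"], 0)
    expect_identical(tf$parametricScale[tf$id == "tranF1"], 1)

    expect_identical(ignoreScansAtStart(spec), 20L)
    expect_identical(repetitionTime(spec), 2000)
    expect_identical(regressorSpecs(spec)$maxLength, c(4e6, 4e6))
    expect_identical(regressorSpecs(spec)$refFct,
                     c("gloverKernel", "gloverKernel"))
    expect_length(validateRules(spec), 0L)
})

test_that("maxLength unit is configurable at parse time", {
    spec <- parseExperiment(adaptiveExampleXml(), lengthUnit = "us")
    expect_identical(regressorSpecs(spec)$maxLength, c(4000, 4000))
})

test_that("a minimal document with no adaptive elements validates cleanly", {
    xml <- '<experiment>
      <mediaObjects>
        <mediaObject moID="m1" name="only" type="IMAGE">
          <contentImage><imageFile>a.jpg</imageFile><posX>0</posX><posY>0</posY></contentImage>
        </mediaObject>
      </mediaObjects>
      <timeTable/>
      <paradigm ignoreScansAtStart="0" tr="2000"/>
    </experiment>'
    spec <- parseExperiment(xml)
    expect_identical(nrow(media(spec)), 1L)
    expect_length(constraints(spec), 0L)
    expect_identical(nrow(regressorSpecs(spec)), 0L)
    expect_length(validateRules(spec), 0L)
})

test_that("violations are reported, not raised, and name the offender", {
    spec <- parseExperiment(adaptiveExampleXml())

    m <- media(spec)
    m$constraintRef[m$id == "PicID1"] <- "co9"
    broken <- experimentSpec(media = m, timetable = timetable(spec),
        systemVariables = systemVariables(spec),
        constraints = constraints(spec),
        transferFunctions = transferFunctions(spec),
        regressorSpecs = regressorSpecs(spec),
        ignoreScansAtStart = ignoreScansAtStart(spec),
        tr = repetitionTime(spec))
    v <- validateRules(broken)
    expect_length(v, 1L)
    expect_match(v, "co9")

    tt <- timetable(spec)
    tt$onset[1] <- -100
    negOnset <- experimentSpec(media = media(spec), timetable = tt,
        systemVariables = systemVariables(spec),
        constraints = constraints(spec),
        transferFunctions = transferFunctions(spec),
        regressorSpecs = regressorSpecs(spec),
        ignoreScansAtStart = ignoreScansAtStart(spec),
        tr = repetitionTime(spec))
    v <- validateRules(negOnset)
    expect_length(v, 1L)
    expect_match(v, "negative onset")
})

test_that("parsing raises on dangling references and malformed numbers", {
    bad <- sub('useConstraint = "co1"', 'useConstraint = "co7"',
               adaptiveExampleXml())
    expect_error(parseExperiment(bad), "co7")
    malformed <- sub('duration = "8"', 'duration = "eight"',
                     adaptiveExampleXml())
    expect_error(parseExperiment(malformed), "eight")
})

test_that("write-then-parse is the identity on the modeled fields", {
    for (s in c(7, 21, 99, 123, 2024)) {
        spec <- makeRandomSpec(s)
        back <- parseExperiment(writeExperiment(spec), validate = FALSE)
        expect_true(isTRUE(specsEqual(spec, back)), label = sprintf(
            "round trip (seed %d), first differing slot: %s", s,
            specsEqual(spec, back)))
    }
    example <- parseExperiment(adaptiveExampleXml())
    back <- parseExperiment(writeExperiment(example))
    expect_true(isTRUE(specsEqual(example, back)))
    empty <- experimentSpec()
    expect_true(isTRUE(specsEqual(empty,
        parseExperiment(writeExperiment(empty)))))
})

test_that("shipped schema accepts generated and example documents", {
    schema <- xml2::read_xml(system.file("extdata", "edl-schema.xsd",
                                         package = "flexstim"))
    example <- system.file("extdata", "example-adaptive-experiment.xml",
                           package = "flexstim")
    expect_true(xml2::xml_validate(xml2::read_xml(example), schema))
    spec <- generateSchedule(syntheticRatings(2, 2, seed = 8), seed = 8,
                             nCandidates = 10)
    expect_true(xml2::xml_validate(xml2::read_xml(writeExperiment(spec)),
                                   schema))
    expect_true(isTRUE(specsEqual(parseExperiment(example),
        parseExperiment(adaptiveExampleXml()))))
})

test_that("serialization writes to file and survives the file system", {
    spec <- parseExperiment(adaptiveExampleXml())
    path <- withr::local_tempfile(fileext = ".xml")
    writeExperiment(spec, path)
    expect_true(isTRUE(specsEqual(spec, parseExperiment(path))))
})
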