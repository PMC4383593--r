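## End-to-end orchestration: paradigm -> closed loop -> design -> GLM ->
## report, single-process at simulated time, with a manifest that makes
## reruns byte-identical.

#' Pipeline run configuration
#'
#' Bundles paths, seed and parameters for [runPipeline()]. Inputs that
#' are `NULL` are synthesized: ratings via [syntheticRatings()], gaze via
#' [simulateGaze()], BOLD via [simulateBold()] with `trueBeta` effects on
#' the four condition regressors.
#'
#' @param outDir output directory (created if missing).
#' @param seed integer; seeds every stochastic stage (recorded in the
#'   manifest).
#' @param specPath optional experiment XML to run instead of generating
#'   one.
#' @param ratings optional rating table or TSV path.
#' @param gazePath optional gaze TSV; otherwise simulated.
#' @param boldPath optional BOLD input (TSV scans x voxels, or NIfTI if
#'   the RNifti package is available); otherwise simulated.
#' @param compliance compliance of the simulated subject.
#' @param nVoxels voxels simulated.
#' @param effectSize true effect (signal units) of each condition
#'   regressor in the first half of the voxels.
#' @param noiseSd,ar1 noise innovation SD and lag-1 autocorrelation.
#' @param contrast contrast for the t-map, see [contrastTMap()].
#' @param fixation a [fixationParams()].
#' @param hrf an [hrfParams()].
#' @param nNegative,nNeutral picture counts when ratings are synthesized.
#' @param nCandidates randomization candidates for [generateSchedule()].
#' @return list of class `runConfig`.
#' @export
runConfig <- function(outDir, seed = 1, specPath = NULL, ratings = NULL,
                      gazePath = NULL, boldPath = NULL, compliance = 0.85,
                      nVoxels = 24, effectSize = 1, noiseSd = 1,
                      ar1 = 0.3, contrast = "REG_NEG_AD-REG_NEUT_AD",
                      fixation = fixationParams(), hrf = hrfParams(),
                      nNegative = 60, nNeutral = 60, nCandidates = 1000) {
    for (p in c(specPath, gazePath, boldPath))
        if (!is.null(p) && !file.exists(p))
            stop(sprintf("input path does not exist: %s", p),
                 call. = FALSE)
    structure(list(outDir = outDir, seed = as.integer(seed),
                   specPath = specPath, ratings = ratings,
                   gazePath = gazePath, boldPath = boldPath,
                   compliance = compliance, nVoxels = nVoxels,
                   effectSize = effectSize, noiseSd = noiseSd, ar1 = ar1,
                   contrast = contrast, fixation = fixation, hrf = hrf,
                   nNegative = nNegative, nNeutral = nNeutral,
                   nCandidates = nCandidates),
              class = "runConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

.isNifti <- function(path)
    grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

.readBold <- function(path) {
    if (.isNifti(path)) {
        if (!requireNamespace("RNifti", quietly = TRUE))
            stop("reading NIfTI input requires the RNifti package",
                 call. = FALSE)
        img <- RNifti::readNifti(path)
        d <- dim(img)
        t(matrix(img, prod(d[1:3]), d[4]))  # scans x voxels
    } else {
        as.matrix(read.delim(path))
    }
}

#' Run the full adaptive-paradigm pipeline
#'
#' Executes paradigm generation (or loading), gaze simulation (or
#' loading), the closed loop, design construction, BOLD simulation (or
#' loading), the GLM with the configured contrast, and the compliance /
#' time-to-valid report. Every artifact is written under
#' `config$outDir`, together with `manifest.json` (package version, seed,
#' configuration echo); rerunning with the same manifest settings
#' reproduces the artifacts byte for byte. Any stage error aborts with
#' the stage name and cause.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with the in-memory objects of the run
#'   (`spec`, `gaze`, `log`, `design`, `fit`, `tmap`, `report`,
#'   `timeToValid`, paths).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    out <- config$outDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)

    spec <- .stage("paradigm", {
        if (!is.null(config$specPath)) {
            parseExperiment(config$specPath)
        } else {
            ratings <- config$ratings
            if (is.null(ratings))
                ratings <- syntheticRatings(config$nNegative,
                                            config$nNeutral,
                                            seed = config$seed)
            else if (is.character(ratings))
                ratings <- read.delim(ratings, stringsAsFactors = FALSE)
            generateSchedule(ratings, seed = config$seed,
                             nCandidates = config$nCandidates)
        }
    })
    writeExperiment(spec, file.path(out, "experiment.xml"))

    plannedEnd <- max(timetable(spec)$onset + timetable(spec)$duration)
    gaze <- .stage("gaze", {
        if (!is.null(config$gazePath)) readGazeStream(config$gazePath)
        else simulateGaze(gazeModel(compliance = config$compliance),
                          duration = plannedEnd +
                              600 * nrow(timetable(spec)) + 60000,
                          seed = config$seed + 1L)
    })
    writeGazeStream(gaze, file.path(out, "gaze.tsv"))

    src <- systemVariables(spec)$source
    providers <- list()
    for (s in unique(src))
        providers[[s]] <- gazeProvider(gaze, config$fixation)
    log <- .stage("closed loop",
                  runClosedLoop(spec, providers, stop = max(gaze$t)))
    writeEventLog(log, file.path(out, "events.tsv"))

    design <- .stage("design",
        buildDesignMatrix(log, spec, hrf = config$hrf))
    write.table(designMatrix(design), file.path(out, "design.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    p <- ncol(designMatrix(design))
    Y <- .stage("bold", {
        if (!is.null(config$boldPath)) .readBold(config$boldPath)
        else {
            beta <- matrix(0, p, config$nVoxels)
            rownames(beta) <- colnames(designMatrix(design))
            active <- seq_len(config$nVoxels %/% 2L)
            for (r in grep("^REG_", rownames(beta)))
                beta[r, active] <- config$effectSize
            beta["intercept", ] <- 0
            simulateBold(design, boldModel(beta, noiseSd = config$noiseSd,
                                           ar1 = config$ar1),
                         seed = config$seed + 2L)
        }
    })
    write.table(Y, file.path(out, "bold.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    fit <- .stage("glm", fitGlm(Y, design))
    tmap <- .stage("contrast", contrastTMap(fit, config$contrast))
    write.table(data.frame(voxel = seq_along(tmap$t), t = tmap$t,
                           effect = tmap$effect, p = tmap$p),
                file.path(out, "tmap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    report <- .stage("report", compliance(log, gaze, config$fixation))
    write.table(report$summary, file.path(out, "compliance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ttv <- timeToValid(report)
    write.table(ttv, file.path(out, "time_to_valid.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "n/a")

    manifest <- list(
        package = "flexstim",
        version = as.character(utils::packageVersion("flexstim")),
        seed = config$seed,
        config = config[!vapply(config, is.function, logical(1))])
    manifest$config$fixation <- unclass(config$fixation)
    manifest$config$hrf <- unclass(config$hrf)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")

    summaryLines <- c(
        sprintf("trials: %d (%d adapted)", sum(!entries(log)$inserted),
                sum(entries(log)$adapted)),
        sprintf("adapted valid fraction: %.3f",
                report$summary$validFraction[
                    report$summary$condition == "adapted"]),
        sprintf("non-adapted valid fraction: %.3f",
                report$nonAdaptedValidFraction),
        sprintf("mean adapted delay: %.1f ms",
                report$summary$meanDelay[
                    report$summary$condition == "adapted"]),
        sprintf("max |t| for %s: %.2f", config$contrast,
                max(abs(tmap$t))))
    writeLines(summaryLines, file.path(out, "summary.txt"))

    invisible(list(spec = spec, gaze = gaze, log = log, design = design,
                   fit = fit, tmap = tmap, report = report,
                   timeToValid = ttv, outDir = out))
}
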