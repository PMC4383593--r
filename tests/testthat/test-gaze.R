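test_that("a constant stream yields one zero-dispersion fixation", {
    s <- makeStream(seq(0, 1000, length.out = 61), 0.2, -0.1)
    fx <- idtFixations(s, fixationParams())
    expect_identical(nrow(fx), 1L)
    expect_identical(fx$tStart, 0)
    expect_identical(fx$tEnd, 1000)
    expect_equal(fx$centroidX, 0.2)
    expect_equal(fx$centroidY, -0.1)
    expect_identical(fx$dispersion, 0)
})

test_that("streams shorter than the duration threshold yield no fixation", {
    s <- makeStream(seq(0, 150, by = 10), 0, 0)
    expect_identical(nrow(idtFixations(s, fixationParams())), 0L)
    expect_identical(nrow(idtFixations(s[0, ], fixationParams())), 0L)
})

test_that("two stationary clusters split by a saccade give two fixations", {
    t1 <- seq(0, 480, by = 16)
    t2 <- seq(600, 1100, by = 16)
    s <- rbind(makeStream(t1, 0.1, 0), makeStream(t2, 5.1, 0))
    p <- fixationParams()
    fx <- idtFixations(s, p)
    expect_identical(nrow(fx), 2L)
    expect_equal(fx, bruteForceFixations(s, p))
})

test_that("I-DT matches the brute-force maximal-window oracle on noisy streams", {
    p <- fixationParams()
    for (seed in 1:12) {
        set.seed(seed)
        # random walk between a few resting points with jitter + dropout
        n <- sample(100:400, 1)
        t <- cumsum(runif(n, 12, 20))
        k <- sample(2:5, 1)
        centers <- cbind(runif(k, -6, 6), runif(k, -6, 6))
        idx <- sort(sample(seq_len(k), n, replace = TRUE))
        s <- data.frame(t = t,
                        x = centers[idx, 1] + rnorm(n, 0, 0.15),
                        y = centers[idx, 2] + rnorm(n, 0, 0.15),
                        valid = runif(n) > 0.03)
        expect_equal(idtFixations(s, p), bruteForceFixations(s, p),
                     label = sprintf("stream seed %d", seed))
    }
})

test_that("every emitted fixation satisfies its own invariants", {
    p <- fixationParams()
    found <- 0L
    for (seed in 20:24) {
        g <- simulateGaze(gazeModel(compliance = 0.6,
                                    dropoutRate = 0.02),
                          duration = 30000, seed = seed)
        fx <- idtFixations(g, p)
        found <- found + nrow(fx)
        expect_true(all(fx$tEnd - fx$tStart >= p$minDuration))
        expect_true(all(fx$dispersion <= p$dispersionThreshold))
        # disjoint and time-ordered
        expect_true(all(diff(as.vector(rbind(fx$tStart, fx$tEnd))) >= 0))
    }
    expect_gt(found, 0L)
})

test_that("the trailing-window fixation test honors all three criteria", {
    p <- fixationParams()
    t <- seq(0, 400, by = 10)

    near <- makeStream(t, 1.9 * cos(0.3), 1.9 * sin(0.3))
    expect_true(isFixated(near, p, 400))     # 1.9 deg eccentric, tight

    far <- makeStream(t, 2.1, 0)
    expect_false(isFixated(far, p, 400))     # centroid beyond 2 deg

    spread <- makeStream(t, 0, 0)
    spread$x <- seq(-1.2, 1.2, length.out = length(t))  # 1.2 deg per window
    expect_false(isFixated(spread, p, 400))  # dispersion 1.2 > 1

    dropout <- makeStream(t, 0, 0)
    dropout$valid[30] <- FALSE
    expect_false(isFixated(dropout, p, 400)) # invalid sample in window

    expect_false(isFixated(makeStream(seq(300, 400, 10), 0, 0), p, 400))
    expect_false(isFixated(makeStream(numeric(0), 0, 0), p, 400))
})

test_that("the gaze provider serves positions and the fixation flag", {
    s <- makeStream(seq(0, 1000, by = 20), 0.7, -0.2)
    s$valid[s$t > 900] <- FALSE
    prov <- gazeProvider(s, fixationParams())
    expect_identical(prov("eyePosX", 950), 0.7)   # latest *valid* sample
    expect_identical(prov("eyePosY", 500), -0.2)
    expect_true(prov("eyePosIsFixated", 800))
    expect_false(prov("eyePosIsFixated", 100))    # window not yet covered
    expect_error(prov("pupilSize", 0), "pupilSize")
})

test_that("pixel streams calibrate to degrees through screen geometry", {
    px <- data.frame(t = 0:2, x = c(0, 100, -100), y = 0, valid = TRUE)
    deg <- pixelsToDegrees(px, screenWidthPx = 1000, screenWidthCm = 40,
                           distanceCm = 60)
    expect_identical(deg$x[1], 0)
    expect_equal(deg$x[2], atan2(4, 60) * 180 / pi)
    expect_equal(deg$x[2], -deg$x[3])
})

test_that("gaze streams survive the TSV round trip", {
    s <- simulateGaze(gazeModel(compliance = 0.6, dropoutRate = 0.05),
                      duration = 3000, seed = 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeGazeStream(s, path)
    expect_equal(readGazeStream(path), s, tolerance = 1e-9)
})
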