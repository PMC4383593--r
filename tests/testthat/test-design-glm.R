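test_that("transfer functions map presented trials to regressor events", {
    tf <- data.frame(id = "tranF1", timeOffset = 0, durationScale = 0,
                     parametricScale = 1)
    entry <- data.frame(actualOnset = 12340, duration = 500)
    ev <- applyTransferFunction(entry, tf)
    expect_identical(ev$onset, 12340)
    expect_identical(ev$duration, 0)   # impulse / event modelling
    expect_identical(ev$weight, 1)

    shifted <- applyTransferFunction(entry,
        data.frame(id = "t", timeOffset = 100, durationScale = 1,
                   parametricScale = 2))
    expect_identical(shifted$onset, 12440)
    expect_identical(shifted$duration, 500)
    expect_identical(shifted$weight, 2)
})

test_that("the haemodynamic kernel has the canonical double-gamma shape", {
    tg <- seq(0, 32, by = 0.01)
    h <- gloverHrf(tg)
    expect_identical(gloverHrf(0), 0)
    expect_equal(max(h), 1)                      # peak-normalized
    peakT <- tg[which.max(h)]
    expect_equal(peakT, 5.4, tolerance = 0.05)   # positive lobe delay
    expect_lt(min(h), 0)                         # undershoot exists
    expect_gt(min(h), -1)
    expect_gt(tg[which.min(h)], peakT)           # undershoot after peak
})

test_that("impulse sampling equals direct kernel evaluation", {
    ev <- data.frame(onset = 0, duration = 0, weight = 1)
    s <- drop(sampleRegressor(ev, tr = 2000, nScans = 12))
    expect_equal(s, gloverHrf(seq(0, 22, by = 2)), tolerance = 1e-12)

    # microtime quantization: an onset shift moves the sampled column
    ev2 <- data.frame(onset = 300, duration = 0, weight = 1)
    s2 <- drop(sampleRegressor(ev2, tr = 2000, nScans = 12))
    expect_equal(s2, gloverHrf(seq(-0.3, 21.7, by = 2)), tolerance = 1e-12)
})

test_that("boxcar sampling matches a direct discrete convolution sum", {
    ev <- data.frame(onset = 1000, duration = 500, weight = 1)
    micro <- 100
    s <- drop(sampleRegressor(ev, tr = 2000, nScans = 20,
                              microtime = micro))
    # oracle: explicit double sum over microtime bins
    nGrid <- 19 * 2000 / micro + 1
    u <- numeric(nGrid)
    u[(1000 / micro + 1):(1500 / micro)] <- 1
    h <- c(gloverHrf(seq(0, 32, by = micro / 1000)), numeric(nGrid))
    direct <- vapply(seq_len(nGrid), function(i)
        sum(u[seq_len(i)] * h[i - seq_len(i) + 1]), numeric(1))
    expect_equal(s, direct[seq(1, nGrid, by = 2000 / micro)],
                 tolerance = 1e-10)
})

test_that("regressor sampling is linear and guards the modeled length", {
    expect_identical(drop(sampleRegressor(
        data.frame(onset = numeric(), duration = numeric(),
                   weight = numeric()), 2000, 10)), numeric(10))
    e1 <- data.frame(onset = 0, duration = 0, weight = 1)
    e2 <- data.frame(onset = 4200, duration = 0, weight = 0.5)
    both <- rbind(e1, e2)
    expect_equal(sampleRegressor(both, 2000, 15),
                 sampleRegressor(e1, 2000, 15) +
                     sampleRegressor(e2, 2000, 15), tolerance = 1e-12)
    expect_error(sampleRegressor(both, 2000, 15, maxLength = 4000),
                 "4000")
})

test_that("derivative and zero-mean columns behave as documented", {
    ev <- data.frame(onset = 0, duration = 0, weight = 1)
    s <- sampleRegressor(ev, tr = 1000, nScans = 25,
                         firstDerivative = TRUE, secondDerivative = TRUE)
    expect_identical(ncol(s), 3L)
    # the sampled derivative column approximates the kernel's slope
    tg <- seq(0, 24, by = 1)
    slope <- (gloverHrf(tg + 0.05) - gloverHrf(pmax(tg - 0.05, 0))) / 0.1
    expect_gt(cor(s[, 2], slope), 0.995)
    z <- sampleRegressor(ev, tr = 1000, nScans = 25, zeroMean = TRUE)
    expect_equal(mean(z[, 1]), 0, tolerance = 1e-12)
})

test_that("the design matrix is assembled from adapted trials", {
    run <- smallAdaptiveRun(nPerClass = 3, complianceLevel = 1, seed = 21)
    d <- buildDesignMatrix(run$log, run$spec)
    X <- designMatrix(d)
    expect_identical(colnames(X), c("REG_NEG_AD", "REG_NEG_NA",
                                    "REG_NEUT_AD", "REG_NEUT_NA",
                                    "intercept"))
    expect_identical(nrow(X), nScans(d) - ignoreScansAtStart(d))
    expect_identical(ignoreScansAtStart(d), 20L)
    expect_true(all(X[, "intercept"] == 1))
    # nuisance covariates are passed through untouched
    nuis <- matrix(rnorm(nScans(d) * 2), ncol = 2,
                   dimnames = list(NULL, c("tx", "ty")))
    d2 <- buildDesignMatrix(run$log, run$spec, nScans = nScans(d),
                            nuisance = nuis)
    expect_identical(designMatrix(d2)[, "tx"],
                     nuis[-seq_len(20), "tx"])
})

test_that("noise-free data recover the coefficients exactly", {
    set.seed(31)
    X <- cbind(a = rnorm(40), b = rnorm(40), intercept = 1)
    d <- new("DesignMatrix", values = X, tr = 2000, nScans = 40L,
             ignoreScansAtStart = 0L)
    beta <- matrix(c(2, -1, 5, 0.5, 3, -2), 3, 2)
    fit <- fitGlm(X %*% beta, d)
    expect_equal(unname(coef(fit)), beta, tolerance = 1e-10)
    expect_equal(fit@sigma2, c(0, 0), tolerance = 1e-12)
    expect_identical(fit@dof, 37L)
})

test_that("leading scans are discarded to match the design", {
    set.seed(32)
    X <- cbind(a = rnorm(100), intercept = 1)
    d <- new("DesignMatrix", values = X, tr = 2000, nScans = 120L,
             ignoreScansAtStart = 20L)
    Yfull <- matrix(rnorm(120), 120, 1)
    fit <- fitGlm(Yfull, d)           # 120 rows in, 100 used
    fitTrim <- fitGlm(Yfull[-(1:20), , drop = FALSE], d)
    expect_identical(coef(fit), coef(fitTrim))
    expect_identical(fit@dof, 98L)
    expect_error(fitGlm(Yfull[1:50, , drop = FALSE], d), "rows")
})

test_that("the incremental fit equals the batch fit after every scan", {
    set.seed(33)
    n <- 30
    X <- cbind(a = rnorm(n), b = runif(n), intercept = 1)
    Y <- matrix(rnorm(n * 3), n, 3)
    acc <- glmAccumulator(colnames(X), nVoxels = 3)
    for (k in seq_len(n)) {
        acc <- addScans(acc, X[k, ], Y[k, ])
        if (k >= 5) {
            d <- new("DesignMatrix", values = X[1:k, , drop = FALSE],
                     tr = 2000, nScans = as.integer(k),
                     ignoreScansAtStart = 0L)
            batch <- fitGlm(Y[1:k, , drop = FALSE], d)
            inc <- glmEstimates(acc)
            expect_equal(coef(inc), coef(batch), tolerance = 1e-10)
            expect_equal(inc@sigma2, batch@sigma2, tolerance = 1e-10)
            expect_identical(inc@dof, batch@dof)
        }
    }
})

test_that("contrast t-statistics follow the Student recipe", {
    set.seed(34)
    n <- 60
    X <- cbind(a = rnorm(n), b = rnorm(n), intercept = 1)
    d <- new("DesignMatrix", values = X, tr = 2000, nScans = 60L,
             ignoreScansAtStart = 0L)
    y <- X %*% c(1, 1, 10) + rnorm(n, 0, 0.5)
    fit <- fitGlm(y, d)
    tm <- contrastTMap(fit, "a-b")
    # oracle: the same contrast through lm() and its covariance matrix
    lmfit <- lm(y ~ a + b, data = as.data.frame(X))
    cvec <- c(0, 1, -1)  # lm order: intercept, a, b
    eff <- sum(cvec * coef(lmfit))
    se <- sqrt(drop(t(cvec) %*% vcov(lmfit) %*% cvec))
    expect_equal(unname(tm$effect), eff, tolerance = 1e-8)
    expect_equal(unname(tm$t), eff / se, tolerance = 1e-8)
    expect_identical(tm$dof, as.integer(df.residual(lmfit)))
    expect_error(contrastTMap(fit, "a-zz"), "zz")

    num <- contrastTMap(fit, c(1, -1, 0))
    expect_equal(num$t, tm$t)
})

test_that("rank-deficient designs fall back to the pseudoinverse", {
    X <- cbind(a = rep(1, 20), b = rep(1, 20))
    d <- new("DesignMatrix", values = X, tr = 2000, nScans = 20L,
             ignoreScansAtStart = 0L)
    expect_warning(fit <- fitGlm(rnorm(20), d), "rank deficient")
    expect_identical(fit@rank, 1L)
    expect_identical(fit@dof, 19L)
})
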