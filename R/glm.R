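## Mass-univariate ordinary least squares, batch and incremental. The
## incremental path accumulates the normal-equations blocks so that a fit
## after k scans reproduces the batch fit on those k scans to floating
## tolerance.

.glmFromNormal <- function(xtx, xty, yty, n, parNames) {
    p <- nrow(xtx)
    qrX <- qr(xtx)
    rank <- qrX$rank
    if (rank < p) {
        warning("design is rank deficient; using pseudoinverse",
                call. = FALSE)
        xtxInv <- MASS::ginv(xtx)
    } else {
        xtxInv <- chol2inv(chol(xtx))
    }
    beta <- xtxInv %*% xty
    rss <- yty - colSums(beta * xty) -
        colSums((xtx %*% beta - xty) * beta)  # exact also when singular
    dof <- as.integer(n - rank)
    sigma2 <- if (dof > 0) pmax(rss, 0) / dof else rep(NA_real_, length(yty))
    rownames(beta) <- parNames
    dimnames(xtxInv) <- list(parNames, parNames)
    new("GlmFit", beta = beta, sigma2 = as.numeric(sigma2), dof = dof,
        xtxInv = xtxInv, rank = as.integer(rank))
}

.asResponseMatrix <- function(Y, design) {
    Y <- as.matrix(Y)
    rows <- nrow(design@values)
    if (nrow(Y) == design@nScans && design@ignoreScansAtStart > 0L)
        Y <- Y[seq.int(design@ignoreScansAtStart + 1L, design@nScans), ,
               drop = FALSE]
    else if (nrow(Y) != rows)
        stop(sprintf("response has %d rows; expected %d (or %d incl. discarded scans)",
                     nrow(Y), rows, design@nScans), call. = FALSE)
    Y
}

#' Fit a general linear model to voxel time series
#'
#' Ordinary least squares per voxel. `Y` may cover the full run (then the
#' first `ignoreScansAtStart` scans are discarded to match the design) or
#' already be trimmed. With a rank-deficient design a pseudoinverse is
#' used and the degrees of freedom reflect the rank.
#'
#' @param Y numeric matrix, scans x voxels (a vector is one voxel).
#' @param design a [DesignMatrix-class].
#' @return A [GlmFit-class] with per-voxel coefficients, residual
#'   variance and the shared `(X'X)^-1` for contrast tests.
#' @examples
#' X <- new("DesignMatrix",
#'          values = cbind(a = rnorm(20), intercept = rep(1, 20)),
#'          tr = 2000, nScans = 20L, ignoreScansAtStart = 0L)
#' fit <- fitGlm(designMatrix(X) %*% c(2, 1), X)
#' coef(fit)
#' @export
fitGlm <- function(Y, design) {
    Y <- .asResponseMatrix(Y, design)
    X <- design@values
    .glmFromNormal(crossprod(X), crossprod(X, Y), colSums(Y^2), nrow(X),
                   colnames(X))
}

#' Incremental GLM accumulation
#'
#' `glmAccumulator()` creates an empty accumulator for `p` parameters and
#' `nVoxels` voxels; `addScans()` folds in one or more scans (rows of the
#' design and the data); `glmEstimates()` solves the accumulated normal
#' equations, yielding exactly the batch fit on the scans seen so far.
#'
#' @param parNames design column names.
#' @param nVoxels number of voxels.
#' @param object a [GlmAccumulator-class].
#' @param x design rows: a length-p vector or a k x p matrix.
#' @param y data rows: a length-nVoxels vector or a k x nVoxels matrix.
#' @return `addScans()` an updated accumulator; `glmEstimates()` a
#'   [GlmFit-class].
#' @examples
#' acc <- glmAccumulator(c("a", "b"), nVoxels = 1)
#' acc <- addScans(acc, c(1, 0.5), 2.1)
#' @name addScans
#' @aliases glmAccumulator
#' @export
glmAccumulator <- function(parNames, nVoxels) {
    p <- length(parNames)
    new("GlmAccumulator",
        xtx = matrix(0, p, p, dimnames = list(parNames, parNames)),
        xty = matrix(0, p, nVoxels), yty = numeric(nVoxels), n = 0L)
}

setMethod("addScans", "GlmAccumulator", function(object, x, y) {
    x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
    y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
    stopifnot(nrow(x) == nrow(y), ncol(x) == nrow(object@xtx),
              ncol(y) == length(object@yty))
    object@xtx <- object@xtx + crossprod(x)
    object@xty <- object@xty + crossprod(x, y)
    object@yty <- object@yty + colSums(y^2)
    object@n <- object@n + nrow(x)
    object
})

setMethod("glmEstimates", "GlmAccumulator", function(object) {
    .glmFromNormal(object@xtx, object@xty, object@yty, object@n,
                   rownames(object@xtx))
})

.parseContrast <- function(contrast, parNames) {
    if (is.numeric(contrast)) {
        if (length(contrast) != length(parNames))
            stop("numeric contrast must have one weight per design column",
                 call. = FALSE)
        return(as.numeric(contrast))
    }
    tokens <- regmatches(contrast,
        gregexpr("[+-]?[^+-]+", gsub("\\s", "", contrast)))[[1L]]
    w <- numeric(length(parNames))
    names(w) <- parNames
    for (tok in tokens) {
        sign <- if (startsWith(tok, "-")) -1 else 1
        name <- sub("^[+-]", "", tok)
        if (!(name %in% parNames))
            stop(sprintf("contrast names unknown design column '%s'", name),
                 call. = FALSE)
        w[name] <- w[name] + sign
    }
    unname(w)
}

#' Contrast t-statistics from a GLM fit
#'
#' Computes `t = c'b / sqrt(sigma2 * c' (X'X)^-1 c)` per voxel. The
#' contrast may be a numeric weight vector over the design columns or a
#' string such as `"REG_NEGDYN-REG_NEUTDYN"` (terms separated by `+`/`-`,
#' each naming a column with weight 1).
#'
#' @param fit a [GlmFit-class].
#' @param contrast numeric vector or contrast string.
#' @return list with `t` (per-voxel t-statistics), `effect` (contrast
#'   estimates), `dof`, and two-sided `p` values from the Student
#'   distribution (uncorrected, as customary at `p < 0.001` style
#'   thresholds).
#' @export
contrastTMap <- function(fit, contrast) {
    w <- .parseContrast(contrast, rownames(fit@beta))
    effect <- drop(crossprod(w, fit@beta))
    varScale <- drop(crossprod(w, fit@xtxInv %*% w))
    se <- sqrt(fit@sigma2 * varScale)
    tvals <- effect / se
    list(t = tvals, effect = effect, dof = fit@dof,
         p = 2 * pt(abs(tvals), df = fit@dof, lower.tail = FALSE))
}
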