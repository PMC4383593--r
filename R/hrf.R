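#' Double-gamma haemodynamic response parameters
#'
#' The canonical difference-of-gammas response: a positive gamma-shaped
#' lobe peaking at `peakShape * peakScale` seconds minus an undershoot
#' lobe peaking at `undershootShape * undershootScale` seconds, weighted
#' by `undershootRatio`. The defaults (peak 5.4 s, undershoot 10.8 s,
#' ratio 0.35) are the standard Glover parameterization; all are
#' overridable.
#'
#' @param peakShape,peakScale shape (dimensionless) and scale (s) of the
#'   positive lobe.
#' @param undershootShape,undershootScale shape and scale of the
#'   undershoot lobe.
#' @param undershootRatio weight of the undershoot relative to the peak.
#' @return list of class `hrfParams`.
#' @export
hrfParams <- function(peakShape = 6, peakScale = 0.9,
                      undershootShape = 12, undershootScale = 0.9,
                      undershootRatio = 0.35) {
    structure(list(peakShape = peakShape, peakScale = peakScale,
                   undershootShape = undershootShape,
                   undershootScale = undershootScale,
                   undershootRatio = undershootRatio),
              class = "hrfParams")
}

.hrfRaw <- function(t, p) {
    t1 <- p$peakShape * p$peakScale
    t2 <- p$undershootShape * p$undershootScale
    pos <- ifelse(t <= 0, 0,
                  (t / t1)^p$peakShape * exp(-(t - t1) / p$peakScale))
    und <- ifelse(t <= 0, 0,
                  (t / t2)^p$undershootShape *
                      exp(-(t - t2) / p$undershootScale))
    pos - p$undershootRatio * und
}

#' Glover-style haemodynamic response kernel
#'
#' Evaluates the difference-of-gammas response at `t` seconds after the
#' impulse, peak-normalized so that the kernel maximum is exactly 1. The
#' value at `t = 0` is 0 (both gamma shapes exceed 1), and the kernel has
#' a post-peak negative undershoot of magnitude below 1.
#'
#' @param t time in seconds (vectorized); values at or before 0 give 0.
#' @param params an [hrfParams()].
#' @return numeric vector of kernel amplitudes.
#' @examples
#' gloverHrf(c(0, 5.4, 11))
#' @export
gloverHrf <- function(t, params = hrfParams()) {
    ## dense-grid normalization: the difference of gammas is not unimodal,
    ## so line search is unreliable
    span <- 4 * max(params$peakShape * params$peakScale,
                    params$undershootShape * params$undershootScale)
    peak <- max(.hrfRaw(seq(0, span, by = 0.005), params))
    .hrfRaw(t, params) / peak
}
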