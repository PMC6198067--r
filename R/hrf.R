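#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout the package: a difference of two gamma
#' densities (response peak near 5 s, undershoot near 15 s), rescaled so the
#' peak amplitude is 1. Zero for `t < 0`.
#'
#' @param t numeric vector of times in seconds.
#' @return numeric vector of HRF amplitudes, peak-normalized to 1.
#' @examples
#' canonical_hrf(c(0, 5, 15))
#' @export
canonical_hrf <- function(t) {
  out <- numeric(length(t))
  pos <- t >= 0
  raw <- function(x) dgamma(x, shape = 6, rate = 1) - dgamma(x, shape = 16, rate = 1) / 6
  out[pos] <- raw(t[pos]) / .hrf_peak_value()
  out
}

.hrf_env <- new.env(parent = emptyenv())
.hrf_peak_value <- function() {
  if (is.null(.hrf_env$peak)) {
    g <- seq(0, 12, by = 1e-3)
    .hrf_env$peak <- max(dgamma(g, 6, 1) - dgamma(g, 16, 1) / 6)
  }
  .hrf_env$peak
}

#' HRF-convolved event regressor sampled at frame times
#'
#' Builds one GLM column: a train of impulses (or boxcars of length
#' `duration_s`) at `onsets`, weighted by `weights`, passed through the
#' canonical HRF and evaluated at `frame_times`. Impulse mode evaluates the
#' HRF analytically at `frame_time - onset`, so the column is exact on any
#' time grid; boxcar mode integrates the HRF over the stimulus epoch on a
#' fine grid.
#'
#' @param onsets event onsets (s), on the same clock as `frame_times`.
#' @param frame_times volume acquisition times (s).
#' @param weights per-event weights (default all 1).
#' @param duration_s event duration; 0 (default) means impulse ("stick") mode.
#' @param dt integration step for boxcar mode (s).
#' @return numeric vector, one value per frame time.
#' @export
hrf_regressor <- function(onsets, frame_times, weights = NULL,
                          duration_s = 0, dt = 0.05) {
  if (is.null(weights)) weights <- rep(1, length(onsets))
  stopifnot(length(weights) == length(onsets))
  col <- numeric(length(frame_times))
  for (e in seq_along(onsets)) {
    lag <- frame_times - onsets[e]
    if (duration_s <= 0) {
      col <- col + weights[e] * canonical_hrf(lag)
    } else {
      s <- seq(0, duration_s, by = dt)
      resp <- rowSums(outer(lag, s, function(l, ss) canonical_hrf(l - ss))) * dt
      col <- col + weights[e] * resp
    }
  }
  col
}
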