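#' @importFrom rlang abort warn %||% .data
#' @importFrom stats approx qt pt sd var cor convolve dgamma rnorm runif rpois
#' @importFrom utils head tail
#' @importFrom graphics hist
NULL

#' Centered moving average with shrinking edge windows
#'
#' Averages each sample over a centered window of `n` samples; near the edges
#' the window is truncated to the available samples, so a constant series is
#' returned unchanged and the output always has the length of the input.
#'
#' @param x numeric vector.
#' @param n window width in samples (>= 1).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, n) {
  stopifnot(n >= 1)
  if (n == 1L || length(x) == 1L) return(x)
  half_lo <- floor((n - 1) / 2)
  half_hi <- ceiling((n - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Trapezoidal integral of sampled curve
#' @keywords internal
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' Linear interpolation with edge-hold extrapolation
#' @keywords internal
interp_edge_hold <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2, ties = "ordered")$y
}

#' Local extrema of a (smoothed) series
#'
#' Finds indices of strict local maxima or minima separated by at least
#' `min_sep` samples, keeping the more extreme of close pairs.
#' @keywords internal
local_extrema <- function(x, what = c("max", "min"), min_sep = 1L) {
  what <- match.arg(what)
  s <- if (what == "max") x else -x
  d <- diff(s)
  # candidate: derivative changes from >=0 to <0 (plateau-tolerant)
  sgn <- sign(d)
  nz <- sgn != 0
  # collapse zero-runs to preceding sign for plateau handling
  run <- sgn
  for (i in seq_along(run)) if (run[i] == 0 && i > 1) run[i] <- run[i - 1]
  cand <- which(head(run, -1) > 0 & tail(run, -1) < 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (idx in cand[-1]) {
    last <- keep[length(keep)]
    if (idx - last >= min_sep) {
      keep <- c(keep, idx)
    } else if (s[idx] > s[last]) {
      keep[length(keep)] <- idx
    }
  }
  keep
}
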