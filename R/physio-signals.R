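#' Detect cardiac pulse peaks in a photoplethysmogram
#'
#' Band-limits the PPG with a short moving average, finds local maxima above
#' an adaptive amplitude threshold, and enforces a 0.3 s refractory period
#' (keeping the larger of two close peaks). A warning is issued when the
#' implied median heart rate leaves the physiological range of 30-200 bpm.
#'
#' @param ppg numeric PPG samples.
#' @param fs sampling rate (Hz), >= 50.
#' @param time optional sample times (s); default `(0:(n-1))/fs`.
#' @param refractory_s minimum peak separation (s).
#' @return strictly increasing numeric vector of peak times (s).
#' @export
detect_cardiac_peaks <- function(ppg, fs, time = NULL, refractory_s = 0.3) {
  if (fs < 50) abort("fs must be >= 50 Hz for pulse detection")
  if (length(ppg) < 5 * fs) abort("need at least 5 s of PPG signal")
  if (var(ppg) == 0) abort("no pulsatile component: PPG signal is flat")
  if (is.null(time)) time <- (seq_along(ppg) - 1) / fs
  x <- moving_average(ppg, max(3L, round(fs * 0.05)))
  thr <- mean(x) + 0.5 * sd(x)
  cand <- local_extrema(x, "max", min_sep = 1L)
  cand <- cand[x[cand] > thr]
  if (length(cand) < 2) abort("no pulsatile component: fewer than 2 pulse peaks found")
  # refractory pruning, keeping the larger peak
  keep <- cand[1]
  for (idx in cand[-1]) {
    last <- keep[length(keep)]
    if (time[idx] - time[last] >= refractory_s) {
      keep <- c(keep, idx)
    } else if (x[idx] > x[last]) {
      keep[length(keep)] <- idx
    }
  }
  peaks <- time[keep]
  rate <- 60 / stats::median(diff(peaks))
  if (rate < 30 || rate > 200) {
    warn(sprintf("implied heart rate %.0f bpm is outside 30-200 bpm", rate))
  }
  peaks
}

# Linear 0 -> 2*pi phase between successive peaks; edge intervals extrapolate
# with the neighbouring period and wrap into [0, 2*pi).
phase_from_peaks <- function(peaks, t_eval) {
  np <- length(peaks)
  idx <- findInterval(t_eval, peaks)
  idx0 <- pmin(pmax(idx, 1L), np - 1L)
  p0 <- peaks[idx0]
  per <- peaks[idx0 + 1L] - p0
  (2 * pi * (t_eval - p0) / per) %% (2 * pi)
}

#' Cardiac phase at evaluation times
#'
#' RETROICOR cardiac phase: 0 at each detected pulse peak, rising linearly to
#' `2*pi` at the next peak. Evaluation times beyond the peak span are phased
#' with the nearest interval's period.
#'
#' @param peaks strictly increasing pulse-peak times (s), length >= 2.
#' @param t_eval evaluation times (s).
#' @return tibble with columns `t`, `phase` (radians in `[0, 2*pi)`), `kind`.
#' @export
cardiac_phase <- function(peaks, t_eval) {
  if (length(peaks) < 2) abort("need at least 2 cardiac peaks")
  if (is.unsorted(peaks, strictly = TRUE)) abort("peaks must be strictly increasing")
  span <- range(peaks)
  margin <- max(diff(peaks))
  if (all(t_eval < span[1] - margin) || all(t_eval > span[2] + margin)) {
    abort("t_eval lies entirely outside the cardiac peak span")
  }
  tibble::tibble(t = t_eval, phase = phase_from_peaks(peaks, t_eval),
                 kind = "cardiac")
}

# Histogram-equalized respiratory phase. `resp_phase_prepare` does the
# trace-level work once (smoothing, amplitude histogram, derivative);
# `resp_phase_eval` is then cheap per evaluation grid, which matters for
# slice-wise regressor construction.
resp_phase_prepare <- function(resp, fs, time, n_bins = 100L) {
  smooth_n <- max(3L, round(fs * 0.25))
  x <- moving_average(resp, smooth_n)
  rng <- range(x)
  if (diff(rng) == 0) abort("constant respiration trace: phase undefined")
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  list(time = time, x = x, breaks = h$breaks,
       cdf = cumsum(h$counts) / sum(h$counts),
       dx = c(diff(x), 0) * fs, n_bins = n_bins)
}

resp_phase_eval <- function(prep, t_eval) {
  amp <- interp_edge_hold(prep$time, prep$x, t_eval)
  bin <- findInterval(amp, prep$breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), prep$n_bins)
  p <- prep$cdf[bin]
  drv <- interp_edge_hold(prep$time, prep$dx, t_eval)
  s <- ifelse(drv < 0, -1, 1)
  ph <- pi * p * s
  ifelse(ph <= -pi, pi, ph)
}

respiratory_phase_core <- function(resp, fs, time, t_eval, n_bins = 100L) {
  resp_phase_eval(resp_phase_prepare(resp, fs, time, n_bins), t_eval)
}

#' Respiratory phase at evaluation times
#'
#' RETROICOR respiratory phase: the respiration amplitude is
#' histogram-equalized (default 100 bins) to a cumulative fraction in
#' `(0, 1]`, scaled to `(0, pi]`, and signed by the derivative of the
#' (lightly smoothed) respiration trace, giving a phase in `(-pi, pi]` that
#' is invariant under amplitude rescaling.
#'
#' @param resp numeric respiration samples.
#' @param fs sampling rate (Hz).
#' @param t_eval evaluation times (s).
#' @param time optional sample times; default `(0:(n-1))/fs`.
#' @param n_bins number of amplitude histogram bins.
#' @return tibble with columns `t`, `phase` (radians in `(-pi, pi]`), `kind`.
#' @export
respiratory_phase <- function(resp, fs, t_eval, time = NULL, n_bins = 100L) {
  if (is.null(time)) time <- (seq_along(resp) - 1) / fs
  if (length(resp) < 4) abort("respiration trace too short")
  tibble::tibble(
    t = t_eval,
    phase = respiratory_phase_core(resp, fs, time, t_eval, n_bins = n_bins),
    kind = "respiratory"
  )
}

# Breath-by-breath RVT (core, shared with the generator):
# (peak - preceding trough) / peak-to-peak period, located at peak times.
compute_rvt_core <- function(resp, fs, time) {
  smooth_n <- max(3L, round(fs * 0.25))
  x <- moving_average(resp, smooth_n)
  min_sep <- max(2L, round(fs * 1.0))
  pk <- local_extrema(x, "max", min_sep = min_sep)
  tr <- local_extrema(x, "min", min_sep = min_sep)
  if (length(pk) < 2 || length(tr) < 1) {
    abort("unable to identify at least two breath peak/trough pairs")
  }
  t_pk <- time[pk]
  rvt <- numeric(length(pk))
  ok <- logical(length(pk))
  for (i in seq_along(pk)) {
    prev_tr <- tr[tr < pk[i]]
    if (!length(prev_tr)) next
    # extrema located on the smoothed trace, amplitudes read from the raw
    # trace so smoothing does not attenuate breath depth
    depth <- resp[pk[i]] - resp[prev_tr[length(prev_tr)]]
    period <- if (i < length(pk)) t_pk[i + 1] - t_pk[i] else t_pk[i] - t_pk[i - 1]
    rvt[i] <- depth / period
    ok[i] <- TRUE
  }
  if (sum(ok) < 2) abort("unable to identify at least two breath peak/trough pairs")
  list(t = t_pk[ok], rvt = pmax(rvt[ok], 0))
}

#' Respiration volume per time (RVT)
#'
#' Breath depth (peak minus preceding trough) divided by the breath period,
#' computed per breath at the peak times, then linearly interpolated to the
#' evaluation times with edge-value extension. For a sinusoid of amplitude
#' `A` and period `T` the RVT is `2A/T` everywhere.
#'
#' @param resp numeric respiration samples.
#' @param fs sampling rate (Hz).
#' @param t_eval evaluation times (s).
#' @param time optional sample times; default `(0:(n-1))/fs`.
#' @return tibble with columns `t`, `rvt` (amplitude units per second, >= 0).
#' @export
compute_rvt <- function(resp, fs, t_eval, time = NULL) {
  if (is.null(time)) time <- (seq_along(resp) - 1) / fs
  core <- compute_rvt_core(resp, fs, time)
  tibble::tibble(t = t_eval, rvt = interp_edge_hold(core$t, core$rvt, t_eval))
}

#' Clean a pupil-diameter recording
#'
#' Invalid (blink/artifact) runs are replaced by linear interpolation between
#' the nearest valid neighbours (edge runs are held at the nearest valid
#' value), then the trace is smoothed with a centered moving average of
#' `smooth_samples` samples. The artifact fraction is the fraction of raw
#' invalid samples; a recording at or above the rejection threshold (default
#' 10%) is flagged `rejected`. Flags are sticky: re-running on a cleaned
#' recording never un-rejects it.
#'
#' @param raw a [pupil_recording()].
#' @param smooth_samples moving-average width (samples).
#' @param reject_threshold artifact fraction at or above which the recording
#'   is flagged rejected.
#' @return a cleaned [pupil_recording()] with fields `artifact_fraction` and
#'   `rejected` updated.
#' @export
preprocess_pupil <- function(raw, smooth_samples = 100L, reject_threshold = 0.10) {
  d <- raw$data
  if (!any(d$valid)) abort("all pupil samples are invalid")
  frac <- mean(!d$valid)
  pd <- d$pd
  if (any(!d$valid)) {
    pd <- interp_edge_hold(d$time[d$valid], pd[d$valid], d$time)
  }
  pd <- moving_average(pd, smooth_samples)
  out <- pupil_recording(
    tibble::tibble(time = d$time, pd = pd, valid = rep(TRUE, nrow(d))),
    fs = raw$fs, trigger_times = raw$trigger_times, t0 = raw$t0,
    rejected = isTRUE(raw$rejected) || frac >= reject_threshold
  )
  out$artifact_fraction <- frac
  out
}

#' Filter a skin conductance trace
#'
#' Rolling median (150 samples, rounded up to the nearest odd window) to
#' remove spikes, followed by a centered 250-sample moving average. Output
#' length equals input length.
#'
#' @param sc numeric skin conductance samples (uS).
#' @param fs sampling rate (Hz) (kept for interface symmetry; windows are in
#'   samples).
#' @param median_samples,smooth_samples filter windows in samples.
#' @return filtered numeric vector, same length as `sc`.
#' @export
preprocess_sc <- function(sc, fs, median_samples = 150L, smooth_samples = 250L) {
  if (length(sc) <= smooth_samples) {
    abort(sprintf("skin conductance trace must exceed %d samples", smooth_samples))
  }
  k <- as.integer(median_samples)
  if (k %% 2L == 0L) k <- k + 1L
  x <- stats::runmed(sc, k, endrule = "median")
  moving_average(as.numeric(x), smooth_samples)
}

#' Synchronize a recording to the retained scan volumes
#'
#' Sets `t = 0` to the scanner trigger of the first retained volume (after
#' discarding the first `n_discard` volumes, default 4), crops the recording
#' to the retained scan duration, and pads with the edge value (with a
#' warning) when the recording ends early. Trigger spacing inconsistent with
#' `n_volumes * tr_s` by more than one TR is an error.
#'
#' @param rec a [physio_recording()] or [pupil_recording()].
#' @param n_volumes acquired volume count (before discarding).
#' @param tr_s repetition time (s).
#' @param n_discard initial volumes discarded to reach steady state.
#' @return the recording, time-shifted and cropped/padded; attributes
#'   `padded` and `n_discard` record what was done.
#' @export
sync_to_scan <- function(rec, n_volumes, tr_s, n_discard = 4L) {
  trig <- rec$trigger_times
  if (!length(trig)) abort("no scanner triggers logged: cannot synchronize")
  if (length(trig) >= 2) {
    span <- trig[length(trig)] - trig[1]
    expected <- (length(trig) - 1) * tr_s
    if (abs(span - expected) > tr_s) {
      abort(sprintf(
        "trigger span %.2f s inconsistent with %d volumes at TR %.3f s (expected %.2f s)",
        span, n_volumes, tr_s, expected))
    }
  }
  t0 <- if (length(trig) > n_discard) trig[n_discard + 1L] else trig[1] + n_discard * tr_s
  dur <- (n_volumes - n_discard) * tr_s
  d <- rec$data
  d$time <- d$time - t0
  d <- d[d$time >= 0 & d$time < dur, , drop = FALSE]
  if (!nrow(d)) abort("recording does not overlap the retained scan window")
  padded <- FALSE
  dt <- 1 / rec$fs
  if (max(d$time) < dur - dt - 1e-9) {
    warn(sprintf("recording ends %.2f s before the scan; padding with edge values",
                 dur - max(d$time)))
    extra_t <- seq(max(d$time) + dt, dur - dt / 2, by = dt)
    pad <- d[rep(nrow(d), length(extra_t)), , drop = FALSE]
    pad$time <- extra_t
    d <- rbind(d, pad)
    padded <- TRUE
  }
  new_trig <- trig[trig >= t0 - 1e-9] - t0
  out <- if (inherits(rec, "pupil_recording")) {
    pupil_recording(d, fs = rec$fs, trigger_times = new_trig, t0 = t0,
                    rejected = isTRUE(rec$rejected))
  } else {
    physio_recording(d, fs = rec$fs, trigger_times = new_trig, t0 = t0)
  }
  attr(out, "padded") <- padded
  attr(out, "n_discard") <- n_discard
  out
}

#' Shift event onsets to the retained-scan clock
#'
#' After discarding the first `n_discard` volumes, event onsets recorded on
#' the acquisition clock must move earlier by `n_discard * tr_s`.
#'
#' @param events event tibble with an `onset` column.
#' @param tr_s repetition time (s).
#' @param n_discard discarded initial volumes.
#' @return the events tibble with shifted onsets.
#' @export
sync_events_to_scan <- function(events, tr_s, n_discard = 4L) {
  events$onset <- events$onset - n_discard * tr_s
  if (any(events$onset < 0)) {
    warn("some events precede the first retained volume")
  }
  events
}

#' Drop initial volumes from a BOLD image
#'
#' @param bold a [bold_image()].
#' @param n_discard number of leading volumes to drop (default 4).
#' @return a [bold_image()] with the remaining volumes.
#' @export
discard_initial_volumes <- function(bold, n_discard = 4L) {
  nv <- n_volumes(bold)
  if (n_discard >= nv) abort("cannot discard all volumes")
  bold_image(bold$data[, , , (n_discard + 1L):nv, drop = FALSE],
             tr_s = bold$tr_s, slice_times = bold$slice_times,
             voxel_dim_mm = bold$voxel_dim_mm)
}
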