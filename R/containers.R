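#' Multichannel peripheral physiological recording
#'
#' Container for peripheral signals sampled at a common rate: a tibble with a
#' `time` column plus one column per channel (typically `ppg`, `respiration`,
#' `sc`), the sampling rate, scanner trigger times, and the scan-start offset
#' `t0` (seconds subtracted from the original clock during synchronization).
#'
#' @param data tibble with a `time` column and channel columns.
#' @param fs sampling rate in Hz.
#' @param trigger_times scanner trigger times (s), non-decreasing.
#' @param t0 scan-start offset already applied to `time` (s).
#' @return an object of class `physio_recording`.
#' @export
physio_recording <- function(data, fs, trigger_times = numeric(0), t0 = 0) {
  stopifnot(is.data.frame(data), "time" %in% names(data), fs > 0)
  if (is.unsorted(trigger_times)) {
    abort("trigger_times must be non-decreasing")
  }
  structure(
    list(data = tibble::as_tibble(data), fs = fs,
         trigger_times = trigger_times, t0 = t0),
    class = "physio_recording"
  )
}

#' Pupil-diameter recording with validity flags
#'
#' @param data tibble with columns `time`, `pd` (pupil diameter) and `valid`
#'   (logical; FALSE marks blink/artifact samples).
#' @param fs sampling rate in Hz.
#' @param trigger_times scanner trigger times (s).
#' @param t0 scan-start offset (s).
#' @param rejected logical; set when the artifact fraction reaches the
#'   rejection threshold (see [preprocess_pupil()]).
#' @return an object of class `pupil_recording` with an `artifact_fraction`
#'   field equal to the fraction of invalid samples.
#' @export
pupil_recording <- function(data, fs, trigger_times = numeric(0), t0 = 0,
                            rejected = FALSE) {
  stopifnot(is.data.frame(data), all(c("time", "pd", "valid") %in% names(data)),
            fs > 0)
  structure(
    list(data = tibble::as_tibble(data), fs = fs,
         trigger_times = trigger_times, t0 = t0,
         artifact_fraction = mean(!data$valid), rejected = rejected),
    class = "pupil_recording"
  )
}

#' 4D BOLD image container
#'
#' Thin wrapper over a 4D array (x, y, z, volume) carrying the repetition
#' time, per-slice acquisition offsets and voxel sizes. The slice axis is the
#' third (slowest-varying) voxel axis.
#'
#' @param data 4D numeric array.
#' @param tr_s repetition time (s).
#' @param slice_times per-slice acquisition offsets within a TR (s); length
#'   must equal `dim(data)[3]`.
#' @param voxel_dim_mm voxel edge lengths (mm), length 3.
#' @return an object of class `bold_image`.
#' @export
bold_image <- function(data, tr_s, slice_times = NULL,
                       voxel_dim_mm = c(1.5, 1.5, 1.5)) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr_s > 0)
  n_slices <- dim(data)[3]
  if (is.null(slice_times)) {
    slice_times <- (seq_len(n_slices) - 1) / n_slices * tr_s
  }
  if (length(slice_times) != n_slices) {
    abort("slice_times length must equal the number of slices (3rd axis)")
  }
  structure(
    list(data = data, tr_s = tr_s, slice_times = slice_times,
         voxel_dim_mm = voxel_dim_mm),
    class = "bold_image"
  )
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels, %d volumes, TR %.3f s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
print.physio_recording <- function(x, ...) {
  ch <- setdiff(names(x$data), "time")
  cat(sprintf("<physio_recording> %d samples @ %g Hz, channels: %s, %d triggers\n",
              nrow(x$data), x$fs, paste(ch, collapse = ", "),
              length(x$trigger_times)))
  invisible(x)
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> %d samples @ %g Hz, artifacts %.1f%%%s\n",
              nrow(x$data), x$fs, 100 * x$artifact_fraction,
              if (isTRUE(x$rejected)) " [REJECTED]" else ""))
  invisible(x)
}

#' Number of volumes in a BOLD image
#' @param bold a [bold_image()].
#' @return integer volume count.
#' @export
n_volumes <- function(bold) dim(bold$data)[4]

#' Volume acquisition times of a BOLD image
#' @param bold a [bold_image()].
#' @return numeric vector `(0:(n-1)) * tr_s`.
#' @export
frame_times <- function(bold) (seq_len(n_volumes(bold)) - 1) * bold$tr_s
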