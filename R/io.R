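#' Write a physiological or pupil recording as BIDS-style TSV + JSON sidecar
#'
#' The TSV holds the sample columns (including `time`); the JSON sidecar
#' records the sampling frequency, column names and scanner trigger times.
#'
#' @param rec a [physio_recording()] or [pupil_recording()].
#' @param path output TSV path; the sidecar replaces `.tsv` with `.json`.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  readr::write_tsv(rec$data, path)
  side <- list(SamplingFrequency = rec$fs, StartTime = rec$t0,
               Columns = names(rec$data), TriggerTimes = rec$trigger_times)
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BIDS-style recording TSV (+ sidecar) back into a recording object
#'
#' @param path TSV path written by [write_recording_tsv()].
#' @return a [physio_recording()] or (when a `pd` column is present) a
#'   [pupil_recording()].
#' @export
read_recording_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  side_path <- sub("\\.tsv$", ".json", path)
  if (!file.exists(side_path)) abort(paste0("missing JSON sidecar for ", path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  trig <- as.numeric(side$TriggerTimes %||% numeric(0))
  if ("pd" %in% names(d)) {
    d$valid <- as.logical(d$valid)
    pupil_recording(d, fs = side$SamplingFrequency, trigger_times = trig,
                    t0 = side$StartTime %||% 0)
  } else {
    physio_recording(d, fs = side$SamplingFrequency, trigger_times = trig,
                     t0 = side$StartTime %||% 0)
  }
}

#' Write a BOLD image as NIfTI-1
#'
#' TR is stored in the 4th pixdim; voxel sizes in the first three.
#'
#' @param bold a [bold_image()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_dim_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 4D series into a BOLD image
#'
#' @param path NIfTI file path.
#' @param slice_times optional per-slice offsets (s); default spreads slices
#'   evenly over the TR.
#' @return a [bold_image()].
#' @export
read_bold_nifti <- function(path, slice_times = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) abort("expected a 4D NIfTI series")
  bold_image(arr, tr_s = pd[4], slice_times = slice_times,
             voxel_dim_mm = pd[1:3])
}

#' Write a 3D map (tSNR, contrast, t) as NIfTI-1
#'
#' @param values 3D array or [tsnr_map()].
#' @param path output path.
#' @param voxel_dim_mm voxel sizes for bare arrays.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, path, voxel_dim_mm = c(1.5, 1.5, 1.5)) {
  if (inherits(values, "tsnr_map")) {
    voxel_dim_mm <- values$voxel_dim_mm
    values <- values$values
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_dim_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic session to a BIDS-inspired directory
#'
#' Emits the BOLD NIfTI, physio/pupil TSVs with JSON sidecars, a BIDS events
#' TSV (onset, duration, trial_type, response_time), a 6-column motion TSV,
#' and the ground truth as JSON.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bold_nifti(session$bold, file.path(dir, "bold.nii.gz"))
  write_recording_tsv(session$physio, file.path(dir, "physio.tsv"))
  write_recording_tsv(session$pupil, file.path(dir, "pupil.tsv"))
  readr::write_tsv(
    dplyr::select(session$events, "onset", "duration", "trial_type",
                  "response_time"),
    file.path(dir, "events.tsv"))
  readr::write_tsv(session$motion, file.path(dir, "motion.tsv"))
  truth <- session$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a BIDS events TSV
#'
#' @param path events TSV with at least `onset`, `duration`, `trial_type`.
#' @return events tibble with a `trial_index` column added.
#' @export
read_events_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(d))) {
    abort(paste0("events TSV must have columns: ", paste(need, collapse = ", ")))
  }
  d$trial_index <- seq_len(nrow(d))
  d
}

#' Write a nuisance regressor set as one TSV per slice
#'
#' @param nuis a `nuisance_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_nuisance_tsv <- function(nuis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(nuis$slice_times)) {
    m <- nuis$values[s, , ]
    colnames(m) <- nuis$names
    readr::write_tsv(tibble::as_tibble(m),
                     file.path(dir, sprintf("nuisance_slice%03d.tsv", s)))
  }
  invisible(dir)
}
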