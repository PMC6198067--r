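.nuisance_names <- function(order = 2L, lags = c(0, 5, 10, 15, 20)) {
  fourier <- function(prefix) {
    unlist(lapply(seq_len(order), function(m) {
      paste0(prefix, c("_cos", "_sin"), m)
    }))
  }
  c(fourier("card"), fourier("resp"), paste0("rvt_lag", lags))
}

#' RETROICOR Fourier basis from cardiac and respiratory phases
#'
#' Low-order Fourier expansion of the two physiological phases:
#' `cos(m*phi)` and `sin(m*phi)` for `m = 1..order` per signal, cardiac
#' columns first. The default order 2 gives the standard 8-column set (four
#' cardiac, four respiratory).
#'
#' @param cardiac,resp phase tibbles from [cardiac_phase()] /
#'   [respiratory_phase()], evaluated on the same time base (the target
#'   slice's acquisition times).
#' @param order Fourier expansion order per signal.
#' @return numeric matrix, `length(t)` rows by `4 * order` named columns,
#'   entries in `[-1, 1]`.
#' @export
retroicor_basis <- function(cardiac, resp, order = 2L) {
  stopifnot(order >= 1)
  if (nrow(cardiac) != nrow(resp) ||
      max(abs(cardiac$t - resp$t)) > 1e-9) {
    abort("cardiac and respiratory phases must share one time base")
  }
  expand <- function(phi) {
    do.call(cbind, lapply(seq_len(order), function(m) {
      cbind(cos(m * phi), sin(m * phi))
    }))
  }
  out <- cbind(expand(cardiac$phase), expand(resp$phase))
  colnames(out) <- .nuisance_names(order, numeric(0))[seq_len(4 * order)]
  out
}

#' Lagged RVT regressors
#'
#' Column `j` evaluates the RVT series at `volume_times - lag_j`, with
#' edge-value extension before the recording start. The default lags 0, 5,
#' 10, 15 and 20 s give the standard 5-column set (the RVT function plus
#' four delayed terms).
#'
#' @param rvt RVT tibble from [compute_rvt()] (columns `t`, `rvt`).
#' @param volume_times acquisition times (s).
#' @param lags_s lag list (s); must be non-empty.
#' @return numeric matrix, `length(volume_times)` rows by `length(lags_s)`
#'   named columns.
#' @export
rvt_regressors <- function(rvt, volume_times, lags_s = c(0, 5, 10, 15, 20)) {
  if (!length(lags_s)) abort("lag list must not be empty")
  out <- vapply(lags_s, function(l) {
    interp_edge_hold(rvt$t, rvt$rvt, volume_times - l)
  }, numeric(length(volume_times)))
  out <- matrix(out, nrow = length(volume_times))
  colnames(out) <- paste0("rvt_lag", lags_s)
  out
}

#' Build the slice-wise physiological nuisance regressor set
#'
#' For each slice, cardiac phase, respiratory phase and RVT are evaluated at
#' that slice's acquisition times `t_k = k * TR + slice_time`, and assembled
#' into the 13-column nuisance set (8 RETROICOR Fourier columns + 5 lagged
#' RVT columns by default). Cardiac peaks are detected from the PPG channel;
#' respiratory quantities come from the respiration channel.
#'
#' @param physio a [physio_recording()] synchronized to the scan (see
#'   [sync_to_scan()]); must cover `n_volumes * tr_s`.
#' @param slice_times per-slice acquisition offsets (s).
#' @param n_volumes retained volume count.
#' @param tr_s repetition time (s).
#' @param retroicor_order Fourier order per signal (default 2).
#' @param rvt_lags_s RVT lags (s).
#' @return an object of class `nuisance_set`: list with `values` (array
#'   slices x volumes x columns), `names`, `slice_times`.
#' @export
build_slicewise_nuisance <- function(physio, slice_times, n_volumes, tr_s,
                                     retroicor_order = 2L,
                                     rvt_lags_s = c(0, 5, 10, 15, 20)) {
  scan_dur <- n_volumes * tr_s
  if (max(physio$data$time) < scan_dur - 1.5 / physio$fs) {
    abort(sprintf("physio recording (%.1f s) shorter than scan (%.1f s)",
                  max(physio$data$time), scan_dur))
  }
  peaks <- detect_cardiac_peaks(physio$data$ppg, physio$fs,
                                time = physio$data$time)
  prep <- resp_phase_prepare(physio$data$respiration, physio$fs,
                             physio$data$time)
  rvt_core <- compute_rvt_core(physio$data$respiration, physio$fs,
                               physio$data$time)
  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  n_cols <- 4L * retroicor_order + length(rvt_lags_s)
  values <- array(NA_real_, dim = c(length(slice_times), n_volumes, n_cols))
  for (s in seq_along(slice_times)) {
    ts <- vol_t + slice_times[s]
    phc <- tibble::tibble(t = ts, phase = phase_from_peaks(peaks, ts),
                          kind = "cardiac")
    phr <- tibble::tibble(t = ts, phase = resp_phase_eval(prep, ts),
                          kind = "respiratory")
    ret <- retroicor_basis(phc, phr, order = retroicor_order)
    rvt <- rvt_regressors(tibble::tibble(t = rvt_core$t, rvt = rvt_core$rvt),
                          ts, lags_s = rvt_lags_s)
    values[s, , ] <- cbind(ret, rvt)
  }
  if (any(!is.finite(values))) abort("non-finite nuisance regressor values")
  structure(
    list(values = values, names = .nuisance_names(retroicor_order, rvt_lags_s),
         slice_times = slice_times),
    class = "nuisance_set"
  )
}

#' @export
print.nuisance_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<nuisance_set> %d slices x %d volumes x %d regressors\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Remove physiological nuisance signal from voxel time series
#'
#' Each voxel's series is replaced by the residual of a least-squares
#' projection onto an intercept plus that voxel's slice's nuisance columns,
#' with the voxel temporal mean restored afterwards (so tSNR before/after is
#' directly comparable). Rank-deficient slice designs drop collinear columns
#' with a warning. Residualization can never increase temporal variance.
#'
#' @param bold a [bold_image()]; the slice axis is the third voxel axis.
#' @param nuis a `nuisance_set` with one row of regressors per slice and as
#'   many volumes as `bold`.
#' @return the corrected [bold_image()], same geometry and TR.
#' @export
residualize <- function(bold, nuis) {
  d <- dim(bold$data)
  if (dim(nuis$values)[1] != d[3]) {
    abort("nuisance set has a different slice count than the image")
  }
  if (dim(nuis$values)[2] != d[4]) {
    abort("nuisance set rows must equal the number of volumes")
  }
  out <- bold$data
  n_sl <- d[3]
  for (s in seq_len(n_sl)) {
    X <- cbind(intercept = 1, nuis$values[s, , ])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warn(sprintf("slice %d: dropped %d collinear nuisance column(s)",
                   s, ncol(X) - qx$rank))
    }
    Y <- matrix(bold$data[, , s, ], nrow = d[1] * d[2], ncol = d[4])
    res <- t(qr.resid(qx, t(Y)))
    res <- res + rowMeans(Y)
    out[, , s, ] <- array(res, dim = c(d[1], d[2], 1, d[4]))
  }
  bold_image(out, tr_s = bold$tr_s, slice_times = bold$slice_times,
             voxel_dim_mm = bold$voxel_dim_mm)
}
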