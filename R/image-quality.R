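#' Voxel-wise temporal signal-to-noise ratio map
#'
#' tSNR is the temporal mean of a voxel's series divided by its temporal
#' standard deviation (sample SD, denominator `n - 1`). Voxels with zero
#' temporal SD are undefined: they are returned as `NA` and flagged in the
#' `defined` grid rather than silently set to 0.
#'
#' @param bold a [bold_image()] with at least 3 volumes.
#' @param mask optional 3D logical array; voxels outside are undefined.
#' @param provenance label stored on the map, e.g. `"corrected"`.
#' @return an object of class `tsnr_map`: list with 3D `values`, logical
#'   `defined`, the `mask`, `voxel_dim_mm` and `provenance`.
#' @export
tsnr_map <- function(bold, mask = NULL, provenance = "uncorrected") {
  d <- dim(bold$data)
  if (d[4] < 3) abort("tSNR needs at least 3 volumes")
  flat <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / (d[4] - 1))
  vals <- ifelse(sdv > 0, mu / sdv, NA_real_)
  defined <- sdv > 0
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == d[1:3]))
    vals[!as.logical(mask)] <- NA_real_
    defined <- defined & as.logical(mask)
  }
  structure(
    list(values = array(vals, d[1:3]), defined = array(defined, d[1:3]),
         mask = mask, voxel_dim_mm = bold$voxel_dim_mm,
         provenance = provenance),
    class = "tsnr_map"
  )
}

#' @export
print.tsnr_map <- function(x, ...) {
  cat(sprintf("<tsnr_map> %s, %d/%d voxels defined, median %.1f\n",
              x$provenance, sum(x$defined), length(x$defined),
              stats::median(x$values[x$defined])))
  invisible(x)
}

#' Voxel-wise tSNR change due to correction
#'
#' @param corrected,uncorrected [tsnr_map()]s on the same grid.
#' @return 3D numeric array `corrected - uncorrected`, `NA` where either map
#'   is undefined.
#' @export
tsnr_change <- function(corrected, uncorrected) {
  if (!all(dim(corrected$values) == dim(uncorrected$values))) {
    abort("tSNR maps are on different grids")
  }
  out <- corrected$values - uncorrected$values
  out[!(corrected$defined & uncorrected$defined)] <- NA_real_
  out
}

#' Summary of a tSNR map within a mask
#'
#' @param map a [tsnr_map()].
#' @param mask 3D logical array; only defined voxels inside the mask are
#'   summarized.
#' @return one-row tibble with `mean`, `sd`, `n_voxels`, `provenance`.
#' @export
mask_summary <- function(map, mask = NULL) {
  sel <- map$defined
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(map$values)))
    sel <- sel & as.logical(mask)
  }
  if (!any(sel)) abort("mask does not overlap any defined voxels")
  v <- map$values[sel]
  tibble::tibble(mean = mean(v), sd = sd(v), n_voxels = sum(sel),
                 provenance = map$provenance)
}

#' @rdname tsnr_map
#' @param x a `tsnr_map`.
#' @param ... unused.
#' @method glance tsnr_map
#' @export
glance.tsnr_map <- function(x, ...) mask_summary(x)
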