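#' Build a first-level design matrix
#'
#' Columns, in order: one HRF-convolved regressor per condition (impulses at
#' stimulus onsets by default; boxcars of the stimulus duration with
#' `stick = FALSE`); for models 2 and 3, one parametrically modulated column
#' per condition (impulses weighted by the per-trial modulator,
#' mean-centered within condition before convolution); six motion
#' parameters; a discrete-cosine high-pass set spanning periods longer than
#' `hp_cutoff_s`; and an intercept last.
#'
#' @param events event tibble (`onset`, `duration`, `trial_type`,
#'   `trial_index`), on the retained-scan clock.
#' @param n_volumes number of retained volumes.
#' @param tr_s repetition time (s).
#' @param model 1 (plain), 2 (SCR-modulated) or 3 (PDR-modulated); models 2
#'   and 3 differ only in where the modulator values come from.
#' @param modulator per-trial modulator values (one per event row), required
#'   iff `model` is 2 or 3.
#' @param motion optional tibble/matrix of 6 motion parameters per volume.
#' @param hp_cutoff_s high-pass cutoff period (s).
#' @param stick TRUE for impulse ("stick") events, FALSE for boxcars of the
#'   stimulus duration.
#' @return an object of class `design_matrix`: list with `values` (volumes x
#'   columns), `column_names`, `frame_times`, `model`, `condition_cols`,
#'   `modulator_cols`, `rank_deficient`.
#' @export
build_design <- function(events, n_volumes, tr_s, model = 1L,
                         modulator = NULL, motion = NULL,
                         hp_cutoff_s = 128, stick = TRUE) {
  if (model %in% c(2L, 3L)) {
    if (is.null(modulator)) abort("models 2 and 3 require a per-trial modulator")
    if (length(modulator) != nrow(events)) {
      abort(sprintf("modulator has %d values for %d trials",
                    length(modulator), nrow(events)))
    }
  } else if (!is.null(modulator)) {
    abort("model 1 does not accept a modulator")
  }
  ft <- (seq_len(n_volumes) - 1) * tr_s
  conds <- sort(unique(events$trial_type))
  dur <- if (stick) 0 else events$duration[1]
  cols <- list()
  for (cc in conds) {
    sel <- events$trial_type == cc
    cols[[cc]] <- hrf_regressor(events$onset[sel], ft, duration_s = dur)
  }
  mod_names <- character(0)
  if (model %in% c(2L, 3L)) {
    for (cc in conds) {
      sel <- events$trial_type == cc
      w <- modulator[sel] - mean(modulator[sel])
      nm <- paste0(cc, "_mod")
      cols[[nm]] <- hrf_regressor(events$onset[sel], ft, weights = w,
                                  duration_s = dur)
      mod_names <- c(mod_names, nm)
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) {
      abort("motion table rows must equal the number of volumes")
    }
    mn <- colnames(motion) %||% paste0("motion", seq_len(ncol(motion)))
    for (j in seq_len(ncol(motion))) cols[[mn[j]]] <- motion[, j]
  }
  n_dct <- floor(2 * n_volumes * tr_s / hp_cutoff_s)
  if (n_dct > 0) {
    i <- seq_len(n_volumes) - 0.5
    for (k in seq_len(n_dct)) {
      cols[[paste0("dct", k)]] <- sqrt(2 / n_volumes) *
        cos(pi * k * i / n_volumes)
    }
  }
  cols[["intercept"]] <- rep(1, n_volumes)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rank_def <- qr(X)$rank < ncol(X)
  if (rank_def) warn("design matrix is rank deficient (flagged)")
  structure(
    list(values = X, column_names = colnames(X), frame_times = ft,
         model = as.integer(model), condition_cols = conds,
         modulator_cols = mod_names, rank_deficient = rank_def),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> model %d: %d volumes x %d columns (%s)\n",
              x$model, nrow(x$values), ncol(x$values),
              paste(x$column_names, collapse = ", ")))
  invisible(x)
}

#' Fit a first-level GLM with AR(1) prewhitening
#'
#' Ordinary least squares is fit per voxel, a single AR(1) coefficient is
#' estimated from the OLS residuals pooled over the analysis mask, both the
#' data and the design are prewhitened by the AR(1) filter (first sample
#' scaled by `sqrt(1 - rho^2)`), and OLS is re-fit on the whitened system.
#' Voxels with non-finite values are masked out with a logged count.
#'
#' The raw pooled lag-1 autocorrelation of OLS residuals is biased towards
#' zero by the projection onto the design; the estimate is debiased by
#' adding back the white-noise expectation of that artefactual
#' autocorrelation, `-tr(A H) / (n - p)` (with `H` the hat matrix and `A`
#' the symmetrized lag-1 shift), which is exactly computable from the
#' design.
#'
#' @param bold a [bold_image()].
#' @param design a [build_design()] result with rows matching the volumes.
#' @param mask optional 3D logical analysis mask.
#' @param ar1_rho optional fixed AR(1) coefficient; bypasses estimation
#'   (0 reproduces the plain OLS fit exactly).
#' @return an object of class `first_level_result` holding per-voxel betas
#'   and residual variances, the whitened `(X'X)^{-1}`, effective df, and
#'   the pooled AR(1) estimate `ar1_rho`.
#' @export
fit_first_level <- function(bold, design, mask = NULL, ar1_rho = NULL) {
  d <- dim(bold$data)
  X <- design$values
  if (nrow(X) != d[4]) abort("design rows must equal the number of volumes")
  n_vox <- prod(d[1:3])
  Y <- t(matrix(bold$data, nrow = n_vox, ncol = d[4]))
  use <- rep(TRUE, n_vox)
  if (!is.null(mask)) use <- use & as.logical(mask)
  finite <- colSums(!is.finite(Y)) == 0
  n_bad <- sum(use & !finite)
  if (n_bad > 0) {
    warn(sprintf("masked out %d voxel(s) with non-finite values", n_bad))
  }
  use <- use & finite
  if (!any(use)) abort("no usable voxels")
  Yu <- Y[, use, drop = FALSE]

  qx <- qr(X)
  n <- nrow(X)
  if (is.null(ar1_rho)) {
    res <- qr.resid(qx, Yu)
    rho_raw <- sum(res[-1, ] * res[-n, ]) / sum(res^2)
    # design-induced bias of the residual lag-1 autocorrelation
    Q <- qr.Q(qx)
    H_offdiag <- rowSums(Q[-n, , drop = FALSE] * Q[-1, , drop = FALSE])
    rho <- rho_raw + sum(H_offdiag) / (n - qx$rank)
    rho <- max(min(rho, 0.99), -0.99)
  } else {
    rho <- ar1_rho
  }

  wh <- function(M) {
    W <- M - rho * rbind(0, M[-n, , drop = FALSE])
    W[1, ] <- sqrt(1 - rho^2) * M[1, ]
    W
  }
  Xw <- wh(X)
  Yw <- wh(Yu)
  qw <- qr(Xw)
  beta <- qr.coef(qw, Yw)
  rss <- colSums(qr.resid(qw, Yw)^2)
  df <- n - qw$rank
  xtx_inv <- chol2inv(qr.R(qw))
  rownames(beta) <- colnames(X)

  structure(
    list(betas = beta, sigma2 = rss / df, xtx_inv = xtx_inv, df_effective = df,
         ar1_rho = rho, design = design, grid = d[1:3], voxel_mask = use,
         voxel_dim_mm = bold$voxel_dim_mm),
    class = "first_level_result"
  )
}

#' @export
print.first_level_result <- function(x, ...) {
  cat(sprintf("<first_level_result> model %d: %d voxels, df %d, AR(1) rho %.3f\n",
              x$design$model, sum(x$voxel_mask), x$df_effective, x$ar1_rho))
  invisible(x)
}

.to_grid <- function(values, grid, voxel_mask) {
  out <- array(NA_real_, grid)
  out[voxel_mask] <- values
  out
}

#' Contrast estimate and t map from a fitted first-level model
#'
#' @param result a [fit_first_level()] result.
#' @param contrast named numeric contrast vector over design columns
#'   (missing columns get weight 0).
#' @return list with 3D arrays `contrast` and `t`, and scalar `df`.
#' @export
contrast_map <- function(result, contrast) {
  cn <- result$design$column_names
  cvec <- stats::setNames(numeric(length(cn)), cn)
  if (is.null(names(contrast))) abort("contrast must be a named vector")
  missing <- setdiff(names(contrast), cn)
  if (length(missing)) {
    abort(paste0("contrast names not in design: ", paste(missing, collapse = ", ")))
  }
  cvec[names(contrast)] <- contrast
  est <- drop(crossprod(cvec, result$betas))
  se <- sqrt(result$sigma2 * drop(crossprod(cvec, result$xtx_inv %*% cvec)))
  list(contrast = .to_grid(est, result$grid, result$voxel_mask),
       t = .to_grid(est / se, result$grid, result$voxel_mask),
       df = result$df_effective)
}

#' Stroop interference contrast (IC vs CC)
#'
#' Model 1 contrasts the main-effect columns (IC - CC); models 2 and 3
#' contrast the parametric-modulator columns (IC_mod - CC_mod), i.e. the
#' interference effect on the autonomic-amplitude-weighted responses.
#'
#' @param result a [fit_first_level()] result.
#' @param model GLM model number; defaults to the design's.
#' @return list with 3D arrays `contrast` and `t`, and scalar `df`.
#' @export
interference_contrast <- function(result, model = result$design$model) {
  cn <- result$design$column_names
  cols <- if (model == 1L) c("CC", "IC") else c("CC_mod", "IC_mod")
  if (!all(cols %in% cn)) {
    abort(paste0("design lacks required columns: ",
                 paste(setdiff(cols, cn), collapse = ", ")))
  }
  contrast_map(result, stats::setNames(c(-1, 1), cols))
}

#' Second-level paired t-test across subjects
#'
#' Voxel-wise paired t on the per-subject (IC - CC) first-level estimates,
#' the paired-test equivalence of a within-subject two-level condition
#' factor; `df = n_subjects - 1`.
#'
#' @param subject_maps_cc,subject_maps_ic lists of 3D arrays, one per
#'   subject, on a common grid.
#' @return an object of class `second_level_result`: list with the group
#'   `t` array, `df`, `n_subjects` and the per-subject difference maps
#'   (used for permutation-based cluster-extent estimation).
#' @export
second_level_paired <- function(subject_maps_cc, subject_maps_ic) {
  if (length(subject_maps_cc) != length(subject_maps_ic)) {
    abort("subject counts differ between conditions")
  }
  n <- length(subject_maps_cc)
  if (n < 3) abort("need at least 3 subjects")
  dims <- dim(subject_maps_cc[[1]])
  ok <- vapply(c(subject_maps_cc, subject_maps_ic),
               function(m) all(dim(m) == dims), logical(1))
  if (!all(ok)) abort("subject maps are on different grids")
  D <- vapply(seq_len(n),
              function(i) as.numeric(subject_maps_ic[[i]] - subject_maps_cc[[i]]),
              numeric(prod(dims)))
  mu <- rowMeans(D)
  sdd <- sqrt(rowSums((D - mu)^2) / (n - 1))
  t_vals <- ifelse(sdd == 0,
                   ifelse(mu == 0, 0, sign(mu) * Inf),
                   mu / (sdd / sqrt(n)))
  structure(
    list(t = array(t_vals, dims), df = n - 1, n_subjects = n,
         diff_maps = D, grid = dims),
    class = "second_level_result"
  )
}

# 26-connectivity connected components via breadth-first flood fill.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  off_lin <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      coord <- arrayInd(v, d)
      nb_ok <- coord[1] + offs[, 1] >= 1 & coord[1] + offs[, 1] <= d[1] &
        coord[2] + offs[, 2] >= 1 & coord[2] + offs[, 2] <= d[2] &
        coord[3] + offs[, 3] >= 1 & coord[3] + offs[, 3] <= d[3]
      ni <- v + off_lin[nb_ok]
      new <- ni[mask[ni] & lab[ni] == 0L]
      if (length(new)) {
        lab[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  lab
}

.cluster_sizes <- function(mask) {
  if (!any(mask)) return(integer(0))
  lab <- label_components(mask)
  tabulate(lab[lab > 0L])
}

#' Threshold a t map into a cluster table
#'
#' Voxels with `t > qt(1 - voxel_p, df)` are labeled by 26-connectivity;
#' clusters at least `extent` voxels large are retained. With
#' `extent = "auto"` the extent threshold is the expected supra-threshold
#' cluster size estimated by sign-flip permutations of the per-subject
#' difference maps (requires a [second_level_paired()] result).
#'
#' @param t_map a `second_level_result` or a 3D t array.
#' @param df degrees of freedom (taken from the result object if given).
#' @param voxel_p uncorrected voxel-level threshold (default 0.005).
#' @param extent `"auto"` or an integer cluster-extent threshold k.
#' @param voxel_dim_mm voxel size for peak coordinates (mm).
#' @param n_permutations sign-flip permutations for `extent = "auto"`.
#' @param seed seed for the permutation stream.
#' @return tibble with one row per retained cluster: `label`,
#'   `size_voxels`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_t`; the
#'   threshold metadata (`voxel_p`, `t_critical`, `extent_k`) is attached as
#'   the `"threshold"` attribute. No supra-threshold voxels gives an empty
#'   table, not an error.
#' @export
cluster_threshold <- function(t_map, df = NULL, voxel_p = 0.005,
                              extent = "auto",
                              voxel_dim_mm = c(1.5, 1.5, 1.5),
                              n_permutations = 1000L, seed = 1L) {
  result <- NULL
  if (inherits(t_map, "second_level_result")) {
    result <- t_map
    t_arr <- result$t
    df <- df %||% result$df
  } else {
    t_arr <- t_map
    if (is.null(df)) abort("df is required when passing a bare t map")
  }
  if (!all(is.finite(t_arr))) abort("t map contains non-finite values")
  t_crit <- qt(1 - voxel_p, df)

  if (identical(extent, "auto")) {
    if (is.null(result)) {
      abort("extent = 'auto' needs a second_level_result (for sign-flip permutations); pass an integer extent otherwise")
    }
    set.seed(seed)
    n <- result$n_subjects
    D <- result$diff_maps
    sizes <- integer(0)
    for (p in seq_len(n_permutations)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      Dp <- sweep(D, 2, s, "*")
      mu <- rowMeans(Dp)
      sdd <- sqrt(rowSums((Dp - mu)^2) / (n - 1))
      tp <- array(mu / (sdd / sqrt(n)), result$grid)
      sizes <- c(sizes, .cluster_sizes(tp > t_crit))
    }
    extent_k <- if (length(sizes)) ceiling(mean(sizes)) else 1L
  } else {
    extent_k <- as.integer(extent)
  }

  supra <- t_arr > t_crit
  empty <- tibble::tibble(label = integer(0), size_voxels = integer(0),
                          peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                          peak_z_mm = numeric(0), peak_t = numeric(0))
  meta <- list(voxel_p = voxel_p, t_critical = t_crit, extent_k = extent_k)
  if (!any(supra)) {
    attr(empty, "threshold") <- meta
    return(empty)
  }
  lab <- label_components(supra)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= extent_k)
  rows <- purrr::map(keep, function(k) {
    vox <- which(lab == k)
    pk <- vox[which.max(t_arr[vox])]
    coord <- arrayInd(pk, dim(t_arr))
    tibble::tibble(label = k, size_voxels = sizes[k],
                   peak_x_mm = (coord[1] - 1) * voxel_dim_mm[1],
                   peak_y_mm = (coord[2] - 1) * voxel_dim_mm[2],
                   peak_z_mm = (coord[3] - 1) * voxel_dim_mm[3],
                   peak_t = t_arr[pk])
  })
  out <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$size_voxels))
  } else empty
  attr(out, "threshold") <- meta
  out
}

#' Overlap between a cluster and an anatomical atlas mask
#'
#' @param cluster logical 3D array or integer vector of linear voxel
#'   indices defining the cluster.
#' @param atlas_mask 3D logical array on the same grid (e.g. an LC atlas
#'   mask).
#' @return one-row tibble: `cluster_size`, `n_overlap`, `fraction`.
#' @export
atlas_overlap <- function(cluster, atlas_mask) {
  if (is.array(cluster) && is.logical(c(cluster[1]))) {
    if (!all(dim(cluster) == dim(atlas_mask))) {
      abort("cluster and atlas mask are on different grids")
    }
    vox <- which(cluster)
  } else {
    vox <- as.integer(cluster)
    if (any(vox < 1 | vox > length(atlas_mask))) {
      abort("cluster voxel indices fall outside the atlas grid")
    }
  }
  inside <- sum(as.logical(atlas_mask)[vox])
  tibble::tibble(cluster_size = length(vox), n_overlap = inside,
                 fraction = inside / length(vox))
}

# 1D Gaussian smoothing with edge renormalization (constant-preserving).
.smooth1d <- function(x, kern) {
  nk <- length(kern)
  half <- (nk - 1) / 2
  num <- stats::convolve(x, rev(kern), type = "open")
  den <- stats::convolve(rep(1, length(x)), rev(kern), type = "open")
  (num / den)[(half + 1):(half + length(x))]
}

#' Spatial Gaussian smoothing at a given FWHM
#'
#' Separable Gaussian filter with `sigma = FWHM / (2 * sqrt(2 * log(2)))`
#' per axis in mm, converted to voxels using the image's voxel sizes. The
#' truncated kernel is renormalized at the edges so a constant image is
#' unchanged.
#'
#' @param img a [bold_image()] or a 3D numeric array.
#' @param fwhm_mm full width at half maximum (mm).
#' @param voxel_dim_mm voxel sizes; required for bare arrays.
#' @return smoothed object of the same type.
#' @export
gaussian_smooth <- function(img, fwhm_mm = 4, voxel_dim_mm = NULL) {
  is_bold <- inherits(img, "bold_image")
  if (is_bold) {
    voxel_dim_mm <- img$voxel_dim_mm
    arr <- img$data
  } else {
    if (is.null(voxel_dim_mm)) abort("voxel_dim_mm is required for bare arrays")
    arr <- img
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kerns <- lapply(voxel_dim_mm, function(vd) {
    s <- sigma_mm / vd
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  })
  smooth3d <- function(vol) {
    d <- dim(vol)
    for (ax in 1:3) {
      vol <- apply(vol, setdiff(1:3, ax), .smooth1d, kern = kerns[[ax]])
      # apply returns the smoothed axis first; rotate back into place
      perm <- order(c(ax, setdiff(1:3, ax)))
      vol <- aperm(array(vol, c(d[ax], d[setdiff(1:3, ax)])), perm)
    }
    vol
  }
  if (length(dim(arr)) == 3) {
    out <- smooth3d(arr)
  } else {
    out <- arr
    for (v in seq_len(dim(arr)[4])) out[, , , v] <- smooth3d(arr[, , , v])
  }
  if (is_bold) {
    bold_image(out, tr_s = img$tr_s, slice_times = img$slice_times,
               voxel_dim_mm = voxel_dim_mm)
  } else {
    out
  }
}
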