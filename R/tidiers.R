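#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a first-level GLM fit
#'
#' One row per design column with the mean and SD of the voxel-wise
#' coefficient estimates over the analysis mask.
#'
#' @param x a [fit_first_level()] result.
#' @param ... unused.
#' @return tibble with `term`, `mean_estimate`, `sd_estimate`.
#' @method tidy first_level_result
#' @export
tidy.first_level_result <- function(x, ...) {
  tibble::tibble(
    term = rownames(x$betas),
    mean_estimate = rowMeans(x$betas),
    sd_estimate = apply(x$betas, 1, sd)
  )
}

#' One-row summary of a first-level GLM fit
#'
#' @param x a [fit_first_level()] result.
#' @param ... unused.
#' @return tibble with `model`, `n_voxels`, `df_effective`, `ar1_rho`.
#' @method glance first_level_result
#' @export
glance.first_level_result <- function(x, ...) {
  tibble::tibble(model = x$design$model, n_voxels = sum(x$voxel_mask),
                 df_effective = x$df_effective, ar1_rho = x$ar1_rho)
}

#' Plot per-condition mean event-related response curves
#'
#' Mean curve with a +/- 1 SD ribbon per condition, in the same layout used
#' to present pupil and skin conductance reactions.
#'
#' @param object a trial-response tibble from [extract_trial_responses()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot trial_responses
#' @export
autoplot.trial_responses <- function(object, ...) {
  plot_condition_curves(object)
}

#' @rdname autoplot.trial_responses
#' @param responses trial-response tibble.
#' @export
plot_condition_curves <- function(responses, ...) {
  summ <- summarize_conditions(responses)
  long <- tidyr::unnest(dplyr::select(summ, "condition", "curve"),
                        cols = "curve")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$mean,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "response (baseline-referenced)",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a tSNR map
#'
#' @param object a [tsnr_map()].
#' @param slice slice index along the third axis (default: middle slice).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tsnr_map
#' @export
autoplot.tsnr_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$tsnr <- as.numeric(object$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$tsnr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("tSNR (%s), slice %d", object$provenance,
                                  slice)) +
    ggplot2::theme_minimal()
}
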