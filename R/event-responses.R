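#' Epoch a cleaned autonomic signal around task events
#'
#' Extracts one response per trial: signal from stimulus onset (`t = 0`) for
#' `window_s` seconds, referenced to the baseline (mean signal over the
#' `baseline_s` seconds before onset). Pupil curves are expressed as a ratio
#' to baseline (a flat signal gives 1.0 everywhere); skin conductance curves
#' are baseline-subtracted in native uS. The area under the curve is the
#' trapezoidal integral of the deflection from the reference (1 for pupil
#' ratios, 0 for SC), in %*s for pupil and uS*s for SC; `auc_samples` is the
#' companion per-sample sum (% or uS per sample) for comparability with
#' sample-count-scaled reports. Trials without a full pre/post window are
#' excluded with a recorded reason.
#'
#' @param signal numeric samples, synchronized to scan time.
#' @param fs sampling rate (Hz).
#' @param events event tibble (columns `onset`, `trial_type`, `trial_index`).
#' @param channel `"pupil"` or `"sc"`.
#' @param time optional sample times (s); default `(0:(n-1))/fs`.
#' @param window_s response window length (s).
#' @param baseline_s pre-onset baseline length (s).
#' @return tibble with one row per trial: `trial_index`, `condition`,
#'   `included`, `exclusion_reason`, `baseline`, `peak`, `peak_latency`,
#'   `auc`, `auc_samples`, and a `curve` list-column of `(t, value)` tibbles.
#' @export
extract_trial_responses <- function(signal, fs, events,
                                    channel = c("pupil", "sc"),
                                    time = NULL, window_s = 10,
                                    baseline_s = 1) {
  channel <- match.arg(channel)
  if (is.null(time)) time <- (seq_along(signal) - 1) / fs
  rows <- purrr::map(seq_len(nrow(events)), function(e) {
    onset <- events$onset[e]
    pre <- time >= onset - baseline_s & time < onset
    post <- time >= onset & time <= onset + window_s
    reason <- NA_character_
    if (sum(pre) < baseline_s * fs * 0.5) reason <- "insufficient pre-onset data"
    if (is.na(reason) && sum(post) < window_s * fs * 0.9) {
      reason <- "insufficient post-onset data"
    }
    base <- tibble::tibble(
      trial_index = events$trial_index[e],
      condition = events$trial_type[e],
      included = is.na(reason), exclusion_reason = reason
    )
    if (!is.na(reason)) {
      return(dplyr::mutate(base, baseline = NA_real_, peak = NA_real_,
                           peak_latency = NA_real_, auc = NA_real_,
                           auc_samples = NA_real_, curve = list(NULL)))
    }
    bl <- mean(signal[pre])
    t_rel <- time[post] - onset
    raw <- signal[post]
    if (channel == "pupil") {
      curve <- raw / bl
      defl <- (curve - 1) * 100
    } else {
      curve <- raw - bl
      defl <- curve
    }
    i_pk <- which.max(curve)
    dplyr::mutate(base,
      baseline = bl, peak = curve[i_pk], peak_latency = t_rel[i_pk],
      auc = trapz(t_rel, defl), auc_samples = sum(defl),
      curve = list(tibble::tibble(t = t_rel, value = curve))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$included)) abort("no extractable trials")
  class(out) <- c("trial_responses", class(out))
  out
}

#' Per-condition mean response curves and summary measures
#'
#' @param responses trial-response tibble from [extract_trial_responses()].
#' @return tibble with one row per condition: `n_trials`, `mean_auc`,
#'   `mean_peak`, and a `curve` list-column of `(t, mean, sd)` tibbles.
#' @export
summarize_conditions <- function(responses) {
  inc <- dplyr::filter(responses, .data$included)
  dplyr::group_by(inc, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_auc = mean(.data$auc),
      mean_peak = mean(.data$peak),
      curve = {
        long <- dplyr::bind_rows(.data$curve, .id = "trial")
        list(dplyr::group_by(long, .data$t) |>
               dplyr::summarise(mean = mean(.data$value),
                                sd = sd(.data$value), .groups = "drop"))
      },
      .groups = "drop"
    )
}

.effect_stats <- function(method, t_statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, estimate = NA_real_,
                          r_squared = NA_real_, n = NA_integer_,
                          degenerate = FALSE) {
  tibble::tibble(method = method, t_statistic = t_statistic, df = df,
                 p_value = p_value, estimate = estimate,
                 r_squared = r_squared, n = n, degenerate = degenerate)
}

#' Paired condition comparison of response measures
#'
#' Paired t-test of per-subject condition means (IC vs CC), `df = n - 1`,
#' two-sided. Input is either a tibble of per-subject means with columns
#' `subject`, `condition`, `value`, or per-trial responses carrying a
#' `subject` column plus the `measure` to aggregate.
#'
#' @param data tibble as described above.
#' @param measure column to aggregate when `data` holds per-trial responses
#'   (e.g. `"auc"` or `"peak"`).
#' @return a one-row effect-stats tibble (`t_statistic`, `df`, `p_value`,
#'   `estimate` = mean IC - CC, `n`, `degenerate`). Zero-variance
#'   differences are reported as an infinite t with `degenerate = TRUE`
#'   rather than an error.
#' @export
compare_conditions <- function(data, measure = "value") {
  if (!"subject" %in% names(data)) {
    abort("data must carry a 'subject' column of per-subject observations")
  }
  if (!"value" %in% names(data)) {
    data <- dplyr::rename(data, value = dplyr::all_of(measure))
  }
  per <- dplyr::group_by(data, .data$subject, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (!all(c("CC", "IC") %in% names(per)) || anyNA(per$CC) || anyNA(per$IC)) {
    abort("both conditions must be present for every subject")
  }
  n <- nrow(per)
  if (n < 3) abort("need at least 3 subjects for a paired comparison")
  d <- per$IC - per$CC
  if (sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(.effect_stats("paired t-test", t_statistic = t_stat, df = n - 1,
                         p_value = if (mean(d) == 0) 1 else 0,
                         estimate = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(per$IC, per$CC, paired = TRUE)
  .effect_stats("paired t-test", t_statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                estimate = unname(tt$estimate), n = n)
}

#' Stroop effect as a percentage increase
#'
#' `100 * (ic - cc) / cc`: the percentage increase of a response measure (or
#' reaction time) from the congruent to the incongruent condition.
#'
#' @param cc_value congruent-condition value, must be > 0.
#' @param ic_value incongruent-condition value.
#' @return percentage (numeric).
#' @examples
#' stroop_effect_percent(1.036, 1.223) # RT interference, ~18%
#' @export
stroop_effect_percent <- function(cc_value, ic_value) {
  if (any(cc_value <= 0)) abort("cc_value must be > 0")
  100 * (ic_value - cc_value) / cc_value
}

#' Habituation trend of responses over trials
#'
#' Standardizes the chosen measure to the first trial (`r_i = x_i / x_1`) and
#' correlates the ratios with trial number (Pearson). A constant series has
#' no defined correlation and is reported as `r_squared = 0` with the
#' `degenerate` flag set.
#'
#' @param responses trial-response tibble (one condition, or filtered via
#'   `condition`).
#' @param measure measure column (default `"auc"`).
#' @param condition optional condition label to filter on.
#' @return one-row effect-stats tibble with `r_squared`, `p_value`,
#'   `estimate` (the slope sign: -1, 0 or 1), `n`.
#' @export
habituation_trend <- function(responses, measure = "auc", condition = NULL) {
  if (!is.null(condition)) {
    responses <- dplyr::filter(responses, .data$condition == !!condition)
  }
  responses <- dplyr::filter(responses, .data$included)
  x <- responses[[measure]][order(responses$trial_index)]
  if (length(x) < 4) abort("need at least 4 trials for a habituation trend")
  if (x[1] == 0) {
    abort("first-trial value is 0: cannot standardize to the first trial (consider mean-standardization)")
  }
  r <- x / x[1]
  idx <- seq_along(r)
  if (sd(r) == 0) {
    return(.effect_stats("habituation trend", p_value = NA_real_,
                         estimate = 0, r_squared = 0, n = length(r),
                         degenerate = TRUE))
  }
  ct <- stats::cor.test(r, idx, method = "pearson")
  .effect_stats("habituation trend",
                t_statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value, estimate = sign(unname(ct$estimate)),
                r_squared = unname(ct$estimate)^2, n = length(r))
}

#' Correlation between two per-subject effect measures
#'
#' Pearson correlation across subjects (e.g. pupillary Stroop effect vs
#' reaction-time interference effect), reported as r-squared with a
#' two-sided p. A leave-one-out sensitivity table is attached as the
#' `"leave_one_out"` attribute.
#'
#' @param x,y numeric per-subject values, equal length >= 3.
#' @return one-row effect-stats tibble (`r_squared`, `p_value`, `n`,
#'   `degenerate` when either input has zero variance).
#' @export
effect_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 subjects")
  if (sd(x) == 0 || sd(y) == 0) {
    return(.effect_stats("effect correlation", r_squared = 0, n = length(x),
                         degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- .effect_stats("effect correlation",
                       t_statistic = unname(ct$statistic),
                       df = unname(ct$parameter), p_value = ct$p.value,
                       estimate = unname(ct$estimate),
                       r_squared = unname(ct$estimate)^2, n = length(x))
  loo <- purrr::map_dbl(seq_along(x), function(i) cor(x[-i], y[-i])^2)
  attr(out, "leave_one_out") <- tibble::tibble(left_out = seq_along(x),
                                               r_squared = loo)
  out
}
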