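#' Ground-truth parameter set for synthetic sessions
#'
#' Collects every parameter the synthetic-session generator needs, so that a
#' single object fully determines a session (identical ground truth implies a
#' bit-identical session). Defaults reproduce the study conditions the
#' pipeline is designed for: a Stroop session of 220 volumes at TR 2.04 s
#' with 18 congruent (CC) and 18 incongruent (IC) trials, incongruent pupil
#' dilations larger than congruent ones, and cardiac/respiratory/RVT-coupled
#' BOLD contamination that lies in the span of the nuisance model.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param hr_bpm mean heart rate (beats/min).
#' @param hr_sd beat-interval jitter SD (s).
#' @param resp_rate breathing rate (breaths/min).
#' @param resp_amp_mod relative breath-amplitude modulation in `[0, 1)`.
#' @param cardiac_gain amplitude of cardiac phase-locked BOLD contamination
#'   (signal units; baseline is 100).
#' @param resp_gain respiratory phase-locked contamination amplitude.
#' @param rvt_gain coupling of lagged RVT to slow BOLD drift.
#' @param beta_cc,beta_ic true activation amplitudes (signal units) per
#'   condition at the active voxels.
#' @param pupil_amp_cc,pupil_amp_ic true pupil dilation amplitudes as a
#'   fraction of baseline diameter. Defaults 0.135 and 0.159 mirror typical
#'   congruent/incongruent peak ratios of about 1.135 and 1.159.
#' @param scr_amp_cc,scr_amp_ic true skin conductance response amplitudes (uS).
#' @param blink_rate blinks per minute in the pupil channel.
#' @param noise_sd thermal noise SD on the BOLD signal (signal units);
#'   peripheral channels receive proportionally scaled measurement noise.
#' @param active_voxel_set integer vector of linear voxel indices carrying
#'   task activation, or NULL to let [gen_bold()] place a central block.
#' @return an object of class `ground_truth` (a validated named list).
#' @export
ground_truth <- function(seed = 1L,
                         hr_bpm = 65, hr_sd = 0.03,
                         resp_rate = 15, resp_amp_mod = 0.1,
                         cardiac_gain = 2, resp_gain = 2, rvt_gain = 1,
                         beta_cc = 1, beta_ic = 2,
                         pupil_amp_cc = 0.135, pupil_amp_ic = 0.159,
                         scr_amp_cc = 0.3, scr_amp_ic = 0.4,
                         blink_rate = 15,
                         noise_sd = 1,
                         active_voxel_set = NULL) {
  rates <- c(hr_bpm = hr_bpm, hr_sd = hr_sd, resp_rate = resp_rate,
             resp_amp_mod = resp_amp_mod, cardiac_gain = cardiac_gain,
             resp_gain = resp_gain, rvt_gain = rvt_gain,
             pupil_amp_cc = pupil_amp_cc, pupil_amp_ic = pupil_amp_ic,
             scr_amp_cc = scr_amp_cc, scr_amp_ic = scr_amp_ic,
             blink_rate = blink_rate, noise_sd = noise_sd)
  if (any(rates < 0)) {
    abort(paste0("ground_truth rates/amplitudes must be >= 0; offending: ",
                 paste(names(rates)[rates < 0], collapse = ", ")))
  }
  if (resp_amp_mod >= 1) abort("resp_amp_mod must be in [0, 1)")
  structure(
    list(seed = as.integer(seed), hr_bpm = hr_bpm, hr_sd = hr_sd,
         resp_rate = resp_rate, resp_amp_mod = resp_amp_mod,
         cardiac_gain = cardiac_gain, resp_gain = resp_gain,
         rvt_gain = rvt_gain, beta_cc = beta_cc, beta_ic = beta_ic,
         pupil_amp_cc = pupil_amp_cc, pupil_amp_ic = pupil_amp_ic,
         scr_amp_cc = scr_amp_cc, scr_amp_ic = scr_amp_ic,
         blink_rate = blink_rate, noise_sd = noise_sd,
         active_voxel_set = active_voxel_set),
    class = "ground_truth"
  )
}

# Derived, non-overlapping RNG streams per generator stage.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage) %% 2147483647L
}

#' Generate a pseudorandomized Stroop event design
#'
#' Produces a trial table with a random permutation of `n_per_condition`
#' congruent ("CC") and incongruent ("IC") trials, stimulus onsets separated
#' by `stim_duration_s + isi_s` plus Gaussian jitter, and simulated reaction
#' times whose condition means reflect Stroop interference (IC slower than
#' CC; defaults 1.223 s vs 1.036 s).
#'
#' @param n_per_condition trials per condition (>= 1).
#' @param stim_duration_s stimulus duration (s).
#' @param isi_s inter-stimulus interval (s).
#' @param jitter_sd_s SD of the Gaussian onset jitter (s); 0 gives exactly
#'   periodic onsets.
#' @param seed integer seed.
#' @param first_onset_s onset of the first trial (s).
#' @param rt_mean_cc,rt_sd_cc,rt_mean_ic,rt_sd_ic reaction-time distribution
#'   parameters (s).
#' @param session_duration_s optional scan duration (s); if the design (last
#'   onset + stimulus) does not fit, an error names the required duration.
#' @return tibble with columns `onset`, `duration`, `trial_type`
#'   (`"CC"`/`"IC"`), `response_time` (s), `trial_index`.
#' @examples
#' gen_event_design(n_per_condition = 18, seed = 7)
#' @export
gen_event_design <- function(n_per_condition = 18L,
                             stim_duration_s = 1.5,
                             isi_s = 10.5,
                             jitter_sd_s = 0.5,
                             seed = 1L,
                             first_onset_s = 12,
                             rt_mean_cc = 1.036, rt_sd_cc = 0.216,
                             rt_mean_ic = 1.223, rt_sd_ic = 0.328,
                             session_duration_s = NULL) {
  stopifnot(n_per_condition >= 1, stim_duration_s > 0, isi_s > 0,
            jitter_sd_s >= 0)
  set.seed(.stage_seed(seed, 11L))
  n <- 2L * n_per_condition
  trial_type <- sample(rep(c("CC", "IC"), each = n_per_condition))
  jitter <- if (jitter_sd_s > 0) rnorm(n - 1, 0, jitter_sd_s) else numeric(n - 1)
  # keep onsets strictly increasing even under extreme jitter draws
  gaps <- pmax(stim_duration_s + isi_s + jitter, stim_duration_s + 0.5)
  onset <- first_onset_s + c(0, cumsum(gaps))
  rt <- ifelse(trial_type == "CC",
               rnorm(n, rt_mean_cc, rt_sd_cc),
               rnorm(n, rt_mean_ic, rt_sd_ic))
  rt <- pmax(rt, 0.2)
  design_end <- onset[n] + stim_duration_s
  if (!is.null(session_duration_s) && design_end > session_duration_s) {
    abort(sprintf(
      "event design needs %.2f s but session is only %.2f s long",
      design_end, session_duration_s))
  }
  tibble::tibble(
    onset = onset, duration = stim_duration_s, trial_type = trial_type,
    response_time = rt, trial_index = seq_len(n)
  )
}

# Bi-exponential SCR kernel: latency `lat`, rise tau_r, decay tau_d,
# normalized to unit peak.
scr_kernel <- function(t, lat = 1.5, tau_r = 0.75, tau_d = 2) {
  u <- t - lat
  k <- numeric(length(t))
  pos <- u > 0
  k[pos] <- exp(-u[pos] / tau_d) - exp(-u[pos] / tau_r)
  t_pk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  peak <- exp(-t_pk / tau_d) - exp(-t_pk / tau_r)
  k / peak
}

# Gamma-shaped pupil dilation kernel, peak amplitude 1 at `peak_s` seconds.
pupil_kernel <- function(t, shape = 3, peak_s = 1) {
  rate <- (shape - 1) / peak_s
  k <- numeric(length(t))
  pos <- t > 0
  k[pos] <- dgamma(t[pos], shape = shape, rate = rate)
  k / dgamma(peak_s, shape = shape, rate = rate)
}

#' Generate peripheral physiological channels
#'
#' Simulates the three polygraph channels: a photoplethysmogram with sharp
#' pulses at hidden ground-truth beat times, a quasi-sinusoidal respiration
#' trace with slow amplitude modulation, and a skin conductance trace built
#' from a slow tonic drift plus one bi-exponential SCR kernel per task event
#' scaled by the condition amplitude. The hidden beat times and breath
#' extrema are attached as attributes for oracle tests.
#'
#' @param truth a [ground_truth()].
#' @param duration_s recording length (s), > 0.
#' @param fs_hz sampling rate (Hz), > 0.
#' @param events optional event tibble from [gen_event_design()]; NULL gives
#'   a tonic-only skin conductance channel.
#' @param trigger_times scanner trigger times to embed (s).
#' @return a [physio_recording()] with attributes `beat_times`,
#'   `breath_peaks`, `breath_troughs`.
#' @export
gen_physio <- function(truth, duration_s, fs_hz = 500, events = NULL,
                       trigger_times = numeric(0)) {
  if (duration_s <= 0) abort("duration_s must be > 0")
  if (fs_hz <= 0) abort("fs_hz must be > 0")
  set.seed(.stage_seed(truth$seed, 23L))
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)

  # cardiac: beat times with jittered intervals, PPG peaks exactly at beats
  mean_ibi <- 60 / truth$hr_bpm
  n_beats <- ceiling(duration_s / mean_ibi) + 5L
  ibi <- pmax(rnorm(n_beats, mean_ibi, truth$hr_sd), 0.25)
  beat_times <- cumsum(c(0, ibi))
  beat_times <- beat_times[beat_times <= duration_s]
  phi <- phase_from_peaks(beat_times, t)
  ppg <- (0.5 + 0.5 * cos(phi))^3

  # respiration: amplitude-modulated sinusoid
  f_resp <- truth$resp_rate / 60
  mod_phase <- runif(1, 0, 2 * pi)
  amp <- 1 + truth$resp_amp_mod * sin(2 * pi * 0.02 * t + mod_phase)
  resp <- amp * sin(2 * pi * f_resp * t)
  k_max <- floor(duration_s * f_resp - 0.25)
  breath_peaks <- (0.25 + 0:max(k_max, 0)) / f_resp
  breath_peaks <- breath_peaks[breath_peaks <= duration_s]
  breath_troughs <- breath_peaks + 0.5 / f_resp
  breath_troughs <- breath_troughs[breath_troughs <= duration_s]

  # skin conductance: tonic drift + event-locked SCRs
  tonic_phase <- runif(1, 0, 2 * pi)
  sc <- 5 + 0.2 * sin(2 * pi * t / 120 + tonic_phase)
  if (!is.null(events)) {
    for (e in seq_len(nrow(events))) {
      amp_e <- if (events$trial_type[e] == "IC") truth$scr_amp_ic else truth$scr_amp_cc
      sc <- sc + amp_e * scr_kernel(t - events$onset[e])
    }
  }

  if (truth$noise_sd > 0) {
    ppg <- ppg + rnorm(length(t), 0, 0.02 * truth$noise_sd)
    resp <- resp + rnorm(length(t), 0, 0.02 * truth$noise_sd)
    sc <- sc + rnorm(length(t), 0, 0.005 * truth$noise_sd)
  }

  rec <- physio_recording(
    tibble::tibble(time = t, ppg = ppg, respiration = resp, sc = sc),
    fs = fs_hz, trigger_times = trigger_times
  )
  attr(rec, "beat_times") <- beat_times
  attr(rec, "breath_peaks") <- breath_peaks
  attr(rec, "breath_troughs") <- breath_troughs
  rec
}

#' Generate a pupil-diameter recording with event-locked dilations
#'
#' Pupil diameter follows a constant baseline times
#' `1 + amplitude * kernel(t - onset)` summed over trials, where the kernel
#' is a gamma-density dilation shape peaking 1 s after stimulus onset and the
#' amplitude is the condition's ground-truth value. Blinks arrive as a
#' Poisson process; blink samples are zeroed and flagged invalid.
#'
#' @param truth a [ground_truth()].
#' @param events event tibble; all events must fit in `duration_s`.
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (Hz).
#' @param baseline_pd baseline pupil diameter (arbitrary units).
#' @param blink_duration_s blink length (s).
#' @param trigger_times scanner trigger times to embed (s).
#' @return a [pupil_recording()]; attribute `trial_amplitudes` holds the true
#'   per-trial dilation amplitudes.
#' @export
gen_pupil <- function(truth, events, duration_s, fs_hz = 120,
                      baseline_pd = 4, blink_duration_s = 0.2,
                      trigger_times = numeric(0)) {
  if (max(events$onset) + events$duration[nrow(events)] > duration_s) {
    abort("events do not fit in the requested pupil recording duration")
  }
  set.seed(.stage_seed(truth$seed, 37L))
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  amps <- ifelse(events$trial_type == "IC", truth$pupil_amp_ic, truth$pupil_amp_cc)
  rel <- rep(1, length(t))
  for (e in seq_len(nrow(events))) {
    rel <- rel + amps[e] * pupil_kernel(t - events$onset[e])
  }
  pd <- baseline_pd * rel
  if (truth$noise_sd > 0) {
    pd <- pd + rnorm(length(t), 0, 0.005 * truth$noise_sd * baseline_pd)
  }
  valid <- rep(TRUE, length(t))
  n_blinks <- rpois(1, truth$blink_rate * duration_s / 60)
  if (n_blinks > 0) {
    starts <- runif(n_blinks, 0, duration_s - blink_duration_s)
    for (b in starts) {
      valid[t >= b & t < b + blink_duration_s] <- FALSE
    }
  }
  frac <- mean(!valid)
  if (frac > 0.5) {
    abort(sprintf("blink_rate renders %.0f%% of samples invalid (> 50%%): unusable recording",
                  100 * frac))
  }
  pd[!valid] <- 0
  rec <- pupil_recording(
    tibble::tibble(time = t, pd = pd, valid = valid),
    fs = fs_hz, trigger_times = trigger_times
  )
  attr(rec, "trial_amplitudes") <- amps
  rec
}

#' Generate a 4D BOLD series with known task signal and physiological noise
#'
#' Voxel time series are a baseline of 100 plus (at active voxels) the
#' HRF-convolved task signal, plus cardiac and respiratory phase-locked
#' Fourier contamination evaluated at each slice's acquisition time, plus a
#' lagged-RVT-coupled drift, plus white thermal noise:
#' \deqn{x_v(t) = 100 + \sum_c \beta_c (h \ast s_c)(t)
#'   + g_c \sum_{m \le 2} [a_m \cos m\varphi_c + b_m \sin m\varphi_c]
#'   + g_r (\ldots \varphi_r \ldots) + g_{rvt} \sum_l w_l RVT(t - l)
#'   + \varepsilon_t.}
#' The contamination is phase-locked to the hidden ground truth of `physio`,
#' so it lies exactly in the span of the RETROICOR + RVT nuisance model and
#' correction can be verified quantitatively.
#'
#' @param truth a [ground_truth()].
#' @param events event tibble driving the task signal.
#' @param physio the [gen_physio()] recording covering the scan.
#' @param n_volumes number of volumes; `physio` must cover
#'   `n_volumes * tr_s`.
#' @param tr_s repetition time (s).
#' @param grid 3D voxel grid dimensions.
#' @param slice_times per-slice acquisition offsets (s); default spreads
#'   slices evenly over the TR.
#' @param voxel_dim_mm voxel size (mm).
#' @return a [bold_image()]; attribute `active_voxel_set` gives the linear
#'   indices of task-active voxels actually used.
#' @export
gen_bold <- function(truth, events, physio, n_volumes = 220L, tr_s = 2.04,
                     grid = c(20L, 20L, 20L), slice_times = NULL,
                     voxel_dim_mm = c(1.5, 1.5, 1.5)) {
  scan_dur <- n_volumes * tr_s
  if (max(physio$data$time) < scan_dur - 1 / physio$fs - 1e-9) {
    abort(sprintf("physio covers %.1f s but the scan needs %.1f s",
                  max(physio$data$time), scan_dur))
  }
  n_slices <- grid[3]
  if (is.null(slice_times)) {
    slice_times <- (seq_len(n_slices) - 1) / n_slices * tr_s
  }
  if (length(slice_times) != n_slices) {
    abort("slice_times must have one entry per slice (grid[3])")
  }
  n_vox <- prod(grid)
  active <- truth$active_voxel_set
  if (is.null(active)) {
    ctr <- pmax(round(grid / 2), 1)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    coords <- sweep(offs, 2, ctr, "+")
    ok <- coords[, 1] >= 1 & coords[, 1] <= grid[1] &
      coords[, 2] >= 1 & coords[, 2] <= grid[2] &
      coords[, 3] >= 1 & coords[, 3] <= grid[3]
    coords <- coords[ok, , drop = FALSE]
    active <- coords[, 1] + (coords[, 2] - 1) * grid[1] +
      (coords[, 3] - 1) * grid[1] * grid[2]
  }
  if (any(active < 1 | active > n_vox)) {
    abort("active_voxel_set contains indices outside the voxel grid")
  }
  set.seed(.stage_seed(truth$seed, 53L))

  vol_t <- (seq_len(n_volumes) - 1) * tr_s
  task_cc <- hrf_regressor(events$onset[events$trial_type == "CC"], vol_t)
  task_ic <- hrf_regressor(events$onset[events$trial_type == "IC"], vol_t)
  task <- truth$beta_cc * task_cc + truth$beta_ic * task_ic

  beats <- attr(physio, "beat_times")
  resp <- physio$data$respiration
  rvt_w <- c(1, 0.8, 0.6, 0.4, 0.2)
  rvt_lags <- c(0, 5, 10, 15, 20)

  # slice-wise nuisance bases from the hidden ground truth
  slice_basis <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    ts <- vol_t + slice_times[s]
    phc <- phase_from_peaks(beats, ts)
    phr <- resp_phase_at(resp, physio$fs, physio$data$time, ts)
    rvt <- rvt_at(resp, physio$fs, physio$data$time, ts, lags = rvt_lags)
    card <- cbind(cos(phc), sin(phc), cos(2 * phc), sin(2 * phc))
    rsp <- cbind(cos(phr), sin(phr), cos(2 * phr), sin(2 * phr))
    slice_basis[[s]] <- list(card = card, resp = rsp,
                             rvt = rvt %*% rvt_w)
  }

  # per-voxel contamination coefficients
  coef_card <- matrix(rnorm(n_vox * 4), n_vox, 4)
  coef_resp <- matrix(rnorm(n_vox * 4), n_vox, 4)
  coef_rvt <- runif(n_vox, 0.5, 1.5)

  dat <- array(0, dim = c(grid, n_volumes))
  flat <- matrix(100, nrow = n_vox, ncol = n_volumes)
  vox_slice <- rep(seq_len(n_slices), each = grid[1] * grid[2])
  for (s in seq_len(n_slices)) {
    idx <- which(vox_slice == s)
    b <- slice_basis[[s]]
    contam <- truth$cardiac_gain * coef_card[idx, , drop = FALSE] %*% t(b$card) +
      truth$resp_gain * coef_resp[idx, , drop = FALSE] %*% t(b$resp) +
      truth$rvt_gain * outer(coef_rvt[idx], drop(b$rvt))
    flat[idx, ] <- flat[idx, ] + contam
  }
  flat[active, ] <- flat[active, ] + matrix(task, nrow = length(active),
                                            ncol = n_volumes, byrow = TRUE)
  if (truth$noise_sd > 0) {
    flat <- flat + matrix(rnorm(n_vox * n_volumes, 0, truth$noise_sd),
                          n_vox, n_volumes)
  }
  dat[] <- flat
  img <- bold_image(dat, tr_s = tr_s, slice_times = slice_times,
                    voxel_dim_mm = voxel_dim_mm)
  attr(img, "active_voxel_set") <- sort(active)
  img
}

# internal hooks used by gen_bold so generator-side phases/RVT use the same
# formulas as the analysis side (defined in physio-signals.R)
resp_phase_at <- function(resp, fs, time, t_eval, n_bins = 100L) {
  respiratory_phase_core(resp, fs, time, t_eval, n_bins = n_bins)
}
rvt_at <- function(resp, fs, time, t_eval, lags) {
  rvt <- compute_rvt_core(resp, fs, time)
  sapply(lags, function(l) interp_edge_hold(rvt$t, rvt$rvt, t_eval - l))
}

#' Generate smooth nuisance motion parameters
#'
#' Six low-amplitude smoothed random walks (three translations in mm, three
#' rotations in radians). Motion is a covariate only; no transformation is
#' applied to the image data.
#'
#' @param n_volumes number of volumes.
#' @param seed integer seed.
#' @return tibble with columns `trans_x..z`, `rot_x..z`.
#' @export
gen_motion <- function(n_volumes, seed = 1L) {
  set.seed(.stage_seed(seed, 71L))
  one <- function(scale) moving_average(cumsum(rnorm(n_volumes, 0, scale)), 10)
  tibble::tibble(
    trans_x = one(0.02), trans_y = one(0.02), trans_z = one(0.02),
    rot_x = one(2e-4), rot_y = one(2e-4), rot_z = one(2e-4)
  )
}

#' Simulate a complete synthetic session
#'
#' Bundles event design, peripheral physiology, pupil recording, BOLD image
#' and motion parameters into one `synthetic_session`, with the generating
#' `ground_truth` attached. Defaults follow the emulated study: 220 volumes
#' at TR 2.04 s, 18 + 18 Stroop trials of 1.5 s with a 10.5 s ISI; the voxel
#' grid defaults to a desk-scale 20 x 20 x 20 volume.
#'
#' @param truth a [ground_truth()].
#' @param n_volumes,tr_s scan geometry.
#' @param grid 3D voxel grid.
#' @param n_per_condition trials per condition.
#' @param fs_physio,fs_pupil peripheral sampling rates (Hz).
#' @param jitter_sd_s onset jitter SD (s).
#' @return an object of class `synthetic_session`: a list with elements
#'   `bold`, `physio`, `pupil`, `events`, `motion`, `truth`.
#' @examples
#' sess <- simulate_session(ground_truth(seed = 2), n_volumes = 40,
#'                          grid = c(6, 6, 4), n_per_condition = 3)
#' sess$events
#' @export
simulate_session <- function(truth = ground_truth(),
                             n_volumes = 220L, tr_s = 2.04,
                             grid = c(20L, 20L, 20L),
                             n_per_condition = 18L,
                             fs_physio = 500, fs_pupil = 120,
                             jitter_sd_s = 0.5) {
  scan_dur <- n_volumes * tr_s
  events <- gen_event_design(n_per_condition = n_per_condition,
                             jitter_sd_s = jitter_sd_s, seed = truth$seed,
                             session_duration_s = scan_dur)
  triggers <- (seq_len(n_volumes) - 1) * tr_s
  physio <- gen_physio(truth, duration_s = scan_dur, fs_hz = fs_physio,
                       events = events, trigger_times = triggers)
  pupil <- gen_pupil(truth, events, duration_s = scan_dur, fs_hz = fs_pupil,
                     trigger_times = triggers)
  bold <- gen_bold(truth, events, physio, n_volumes = n_volumes, tr_s = tr_s,
                   grid = grid)
  motion <- gen_motion(n_volumes, seed = truth$seed)
  truth$active_voxel_set <- attr(bold, "active_voxel_set")
  structure(
    list(bold = bold, physio = physio, pupil = pupil, events = events,
         motion = motion, truth = truth),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> seed %d: %d volumes, %d trials, grid %s\n",
              x$truth$seed, n_volumes(x$bold), nrow(x$events),
              paste(dim(x$bold$data)[1:3], collapse = "x")))
  invisible(x)
}
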