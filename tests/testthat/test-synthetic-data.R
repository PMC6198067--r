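test_that("event design has exact per-condition counts and valid ordering", {
  ev <- gen_event_design(n_per_condition = 18, stim_duration_s = 1.5,
                         isi_s = 10.5, seed = 5)
  expect_equal(nrow(ev), 36)
  expect_equal(sum(ev$trial_type == "CC"), 18)
  expect_equal(sum(ev$trial_type == "IC"), 18)
  expect_true(!is.unsorted(ev$onset, strictly = TRUE))
  # jitter-free onsets are exactly duration + ISI apart
  ev0 <- gen_event_design(n_per_condition = 5, jitter_sd_s = 0, seed = 1)
  expect_equal(diff(ev0$onset), rep(12.0, 9))
})

test_that("event design is seed-deterministic and seed-sensitive", {
  a <- gen_event_design(10, seed = 42)
  b <- gen_event_design(10, seed = 42)
  c <- gen_event_design(10, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$trial_type, c$trial_type) &&
                 identical(a$onset, c$onset))
})

test_that("event design errors when it cannot fit the session", {
  expect_error(gen_event_design(18, seed = 1, session_duration_s = 60),
               "needs [0-9.]+ s")
})

test_that("physio generator produces exact rhythms in the noiseless limit", {
  truth <- ground_truth(seed = 1, hr_bpm = 60, hr_sd = 0, resp_rate = 15,
                        resp_amp_mod = 0, noise_sd = 0)
  rec <- gen_physio(truth, duration_s = 60, fs_hz = 500)
  beats <- attr(rec, "beat_times")
  expect_equal(diff(beats), rep(1.0, length(beats) - 1))
  # respiration is a pure sinusoid of period 4 s
  t <- rec$data$time
  expect_equal(rec$data$respiration, sin(2 * pi * t / 4), tolerance = 1e-12)
})

test_that("SCR peak amplitudes scale with the condition amplitude", {
  ev <- gen_event_design(3, seed = 2, isi_s = 20)
  truth <- ground_truth(seed = 2, scr_amp_cc = 0.25, scr_amp_ic = 0.5,
                        noise_sd = 0)
  rec <- gen_physio(truth, duration_s = 140, fs_hz = 100, events = ev)
  # same seed without events reproduces the identical tonic component, so the
  # difference isolates the pure event-locked SCR sum
  rec0 <- gen_physio(truth, duration_s = 140, fs_hz = 100)
  scr <- rec$data$sc - rec0$data$sc
  peak_of <- function(onset) {
    max(scr[rec$data$time >= onset & rec$data$time <= onset + 10])
  }
  pk <- vapply(ev$onset, peak_of, numeric(1))
  ratio <- mean(pk[ev$trial_type == "IC"]) / mean(pk[ev$trial_type == "CC"])
  expect_equal(ratio, 2, tolerance = 0.01)
  # kernel peak evaluates analytically to the condition amplitude
  expect_equal(max(pk), 0.5, tolerance = 0.01)
})

test_that("physio generator rejects non-positive duration and rate", {
  truth <- ground_truth()
  expect_error(gen_physio(truth, duration_s = 0), "duration")
  expect_error(gen_physio(truth, duration_s = 10, fs_hz = -1), "fs_hz")
})

test_that("noiseless pupil traces separate conditions trial by trial", {
  ev <- gen_event_design(6, seed = 3)
  truth <- ground_truth(seed = 3, blink_rate = 0, noise_sd = 0,
                        pupil_amp_cc = 0.1, pupil_amp_ic = 0.2)
  rec <- gen_pupil(truth, ev, duration_s = max(ev$onset) + 15)
  peak_of <- function(onset) {
    win <- rec$data$time >= onset & rec$data$time <= onset + 10
    max(rec$data$pd[win]) / 4
  }
  pk <- vapply(ev$onset, peak_of, numeric(1))
  expect_true(min(pk[ev$trial_type == "IC"]) > max(pk[ev$trial_type == "CC"]))
})

test_that("zero-amplitude pupil response is constant at baseline", {
  ev <- gen_event_design(3, seed = 4)
  truth <- ground_truth(seed = 4, blink_rate = 0, noise_sd = 0,
                        pupil_amp_cc = 0, pupil_amp_ic = 0)
  rec <- gen_pupil(truth, ev, duration_s = max(ev$onset) + 15)
  expect_equal(rec$data$pd, rep(4, nrow(rec$data)))
})

test_that("invalid-sample fraction matches the blink-rate expectation", {
  # expected fraction = blink_rate * blink_duration / 60
  ev <- gen_event_design(3, seed = 1)
  dur <- max(ev$onset) + 15
  rate <- 20; bdur <- 0.2
  expected <- rate * bdur / 60
  fracs <- vapply(1:20, function(s) {
    truth <- ground_truth(seed = s, blink_rate = rate, noise_sd = 0)
    gen_pupil(truth, ev, duration_s = dur,
              blink_duration_s = bdur)$artifact_fraction
  }, numeric(1))
  n_tot <- 20 * dur * 120
  se <- sqrt(expected * (1 - expected) / n_tot)
  # overlap between blinks makes the realized fraction slightly lower
  expect_lt(abs(mean(fracs) - expected), max(3 * se, 0.1 * expected))
})

test_that("unusably blink-dense pupil recordings are refused", {
  ev <- gen_event_design(2, seed = 1)
  truth <- ground_truth(seed = 1, blink_rate = 2000)
  expect_error(gen_pupil(truth, ev, duration_s = max(ev$onset) + 15),
               "unusable")
})

test_that("gen_bold is constant without signal and exact within the Fourier span", {
  ev <- gen_event_design(2, seed = 5, isi_s = 8)
  truth0 <- ground_truth(seed = 5, cardiac_gain = 0, resp_gain = 0,
                         rvt_gain = 0, beta_cc = 0, beta_ic = 0, noise_sd = 0)
  phys <- gen_physio(truth0, duration_s = 82, fs_hz = 200)
  img <- gen_bold(truth0, ev, phys, n_volumes = 40, tr_s = 2,
                  grid = c(4, 4, 2))
  expect_equal(max(voxel_variances(img)), 0)

  # cardiac contamination only: residual variance after projecting onto the
  # true order-2 Fourier basis is numerically zero
  truth1 <- ground_truth(seed = 5, cardiac_gain = 1, resp_gain = 0,
                         rvt_gain = 0, beta_cc = 0, beta_ic = 0, noise_sd = 0)
  phys1 <- gen_physio(truth1, duration_s = 82, fs_hz = 200)
  img1 <- gen_bold(truth1, ev, phys1, n_volumes = 40, tr_s = 2,
                   grid = c(4, 4, 2), slice_times = rep(0, 2))
  beats <- attr(phys1, "beat_times")
  phi <- cardiac_phase(beats, (0:39) * 2)$phase
  X <- cbind(1, cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  y <- img1$data[2, 3, 1, ]
  res <- lm.fit(X, y)$residuals
  expect_lt(var(res) / var(y), 1e-20)
})

test_that("gen_bold validates its geometry and coverage", {
  ev <- gen_event_design(2, seed = 1, isi_s = 8)
  truth <- ground_truth(seed = 1)
  phys <- gen_physio(truth, duration_s = 82, fs_hz = 100)
  expect_error(gen_bold(truth, ev, phys, n_volumes = 40, tr_s = 2,
                        grid = c(4, 4, 2), slice_times = c(0, 0.5, 1)),
               "slice")
  expect_error(gen_bold(truth, ev, phys, n_volumes = 100, tr_s = 2,
                        grid = c(4, 4, 2)), "scan needs")
  truth_bad <- ground_truth(seed = 1, active_voxel_set = c(1, 9999))
  expect_error(gen_bold(truth_bad, ev, phys, n_volumes = 40, tr_s = 2,
                        grid = c(4, 4, 2)), "outside the voxel grid")
})

test_that("identical ground truth reproduces an identical session", {
  a <- quiet_session(seed = 11)
  b <- quiet_session(seed = 11)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$physio$data, b$physio$data)
  expect_identical(a$pupil$data, b$pupil$data)
  expect_identical(a$events, b$events)
  expect_identical(a$motion, b$motion)
})

test_that("session invariants hold: triggers equal volumes, physio covers scan", {
  sess <- quiet_session(seed = 12)
  expect_equal(length(sess$physio$trigger_times), n_volumes(sess$bold))
  expect_gte(max(sess$physio$data$time),
             n_volumes(sess$bold) * sess$bold$tr_s - 1 / sess$physio$fs - 1e-9)
})

test_that("sessions round-trip through the BIDS-style on-disk layout", {
  sess <- suppressWarnings(
    simulate_session(ground_truth(seed = 9), n_volumes = 30,
                     grid = c(4, 4, 2), n_per_condition = 2))
  dir <- withr::local_tempdir()
  write_session(sess, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "bold.nii.gz", "physio.tsv", "physio.json", "pupil.tsv",
    "events.tsv", "motion.tsv", "ground_truth.json")))))
  bold2 <- read_bold_nifti(file.path(dir, "bold.nii.gz"))
  expect_equal(bold2$data, unclass(sess$bold$data), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(bold2$tr_s, sess$bold$tr_s, tolerance = 1e-6)
  phys2 <- read_recording_tsv(file.path(dir, "physio.tsv"))
  expect_s3_class(phys2, "physio_recording")
  expect_equal(phys2$fs, sess$physio$fs)
  pup2 <- read_recording_tsv(file.path(dir, "pupil.tsv"))
  expect_s3_class(pup2, "pupil_recording")
  ev2 <- read_events_tsv(file.path(dir, "events.tsv"))
  expect_equal(ev2$onset, sess$events$onset)
})
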