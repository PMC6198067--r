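---
title: "Physiological noise correction and physiologically informed GLMs for brainstem fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological noise correction and physiologically informed GLMs for brainstem fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiofmri)
```

## The problem

Brainstem and midbrain nuclei — the locus coeruleus (LC), substantia nigra
(SN), periaqueductal gray — are a few millimetres across and sit next to
large arteries and cerebrospinal-fluid spaces. Cardiac pulsation and
respiration therefore contaminate their BOLD time series far more than
cortical voxels, and task effects in these nuclei are easily drowned or
mimicked by physiological noise. This package implements the analysis chain
needed to study such nuclei with event-related task fMRI:

1. peripheral-signal preprocessing (photoplethysmogram, respiration belt,
   skin conductance at 500 Hz; video pupillometry at 120 Hz), synchronized
   to the scanner triggers;
2. model-based physiological noise correction: slice-wise RETROICOR Fourier
   regressors plus lagged respiration-volume-per-time (RVT) terms, removed
   from every voxel's series by least-squares projection;
3. temporal signal-to-noise ratio (tSNR) mapping to quantify what the
   correction bought;
4. event-related autonomic response quantification (pupil dilation response,
   PDR; skin conductance response, SCR) around Stroop trials;
5. first- and second-level GLMs for the Stroop interference contrast
   (incongruent IC vs congruent CC), optionally with each trial's regressor
   weighted by its autonomic response amplitude (parametric modulation), and
   cluster-extent thresholding with atlas-mask overlap.

Because no suitable public dataset ships raw brainstem BOLD together with
synchronized polygraph and eye-tracker traces, the package is validated
end-to-end on its own synthetic-session generator with known ground truth.

## The nuisance model

For each slice, acquired at offset $\delta_s$ within the TR, cardiac phase
$\varphi_c(t)$ and respiratory phase $\varphi_r(t)$ are evaluated at the
slice's acquisition times $t_k = k\,\mathrm{TR} + \delta_s$. The nuisance
set has 13 columns:

* 8 RETROICOR terms: $\cos m\varphi_c$, $\sin m\varphi_c$,
  $\cos m\varphi_r$, $\sin m\varphi_r$ for $m = 1, 2$;
* 5 RVT terms: the RVT series evaluated at lags 0, 5, 10, 15 and 20 s.

Cardiac phase rises linearly from 0 to $2\pi$ between successive pulse
peaks detected on the PPG. Respiratory phase is the histogram-equalized
amplitude transform (100 bins, configurable), scaled to $(0, \pi]$ and
signed by the derivative of the respiration trace, so it is invariant under
amplitude rescaling. RVT is breath depth (peak minus preceding trough)
divided by the peak-to-peak period, assigned at peak times and linearly
interpolated with edge-value extension; extrema are located on a lightly
smoothed trace but depths are read from the raw trace so smoothing does not
attenuate them. For a sinusoidal breath of amplitude $A$ and period $T$,
RVT is $2A/T$, which the tests verify to better than 1%.

Correction projects each voxel's series onto an intercept plus its slice's
13 regressors and keeps the residual, with the voxel's temporal mean added
back so tSNR is comparable before and after. Projection can only reduce
temporal variance; the tests assert this voxel-wise. Lags that reach before
the recording start use edge-hold values, the least surprising convention
for the first volumes where a 20 s delayed regressor is undefined. Motion
parameters are deliberately *not* part of this stage; they enter the GLM as
covariates.

## Timing conventions

The first four acquired volumes are discarded (steady-state magnetization);
`sync_to_scan()` re-zeroes every recording at the trigger of the first
retained volume, crops to the retained duration (216 of 220 volumes at
TR 2.04 s, i.e. 440.64 s at the default session geometry), and pads a
too-short recording with edge values under an explicit warning. Event
onsets move earlier by four TRs via `sync_events_to_scan()`. Trigger
spacing inconsistent with the claimed geometry by more than one TR is an
error, not a warning.

## Peripheral-signal preprocessing

* **PPG**: pulse peaks via a 50 ms moving-average band-limit, an adaptive
  amplitude threshold (mean + 0.5 SD), and a 0.3 s refractory period. The
  acquisition hardware's published analog filtering (0.05–3 Hz) makes this
  simple scheme reliable at 500 Hz; detection on clean synthetic pulses is
  accurate to a few milliseconds.
* **Pupil**: invalid (blink/artifact) runs are replaced by linear
  interpolation between nearest valid neighbours, then smoothed with a
  centered 100-sample moving average. A recording whose *raw* invalid
  fraction reaches 10% is flagged rejected — the strict reading of an
  inclusion rule of "less than 10% artifacts", tested exactly at the
  boundary. Interpolated samples are not counted toward the fraction. The
  flag is sticky: cleaning never un-rejects a recording.
* **Skin conductance**: 150-sample rolling median (rounded up to the odd
  151 required by a running median) followed by a centered 250-sample
  moving average. "Smoothed over N samples" is read throughout as a
  centered moving average with shrinking windows at the edges, the simplest
  reading of acquisition-software smoothing; constants are arguments, not
  hard-coded.

## Event-related responses

Responses are epoched from stimulus onset for 10 s against a baseline of
the mean signal in the 1 s before onset. Pupil curves are *ratios* to
baseline — peak values around 1.13–1.16 in normalized units for typical
dilations — making them invariant to the eye-tracker's arbitrary diameter
units; SC curves are baseline-subtracted in native µS. The area under the
curve is the trapezoidal integral of the deflection (%·s for pupil, µS·s
for SC); a per-sample sum variant (`auc_samples`) is also emitted because
published AUC magnitudes in "normalized units" are consistent with summing
percent deflections over 120 Hz samples in the 10 s window, and emitting
both avoids guessing which construction a given report used. Condition
comparisons are paired t-tests across subjects on per-subject means
(df = n − 1); the Stroop effect on any measure is $100\,(IC - CC)/CC$;
habituation standardizes AUCs to the first trial and correlates the ratios
with trial number. Degenerate inputs (zero-variance differences, constant
AUC series) are reported with flags, never silent errors.

## The GLM

The canonical HRF is the usual double-gamma difference (peak ≈ 5 s,
undershoot ≈ 15 s), peak-normalized. Event regressors are impulses at
onsets passed through the HRF and evaluated analytically at frame times
(the default, matching a model of "impulses at stimulus onset"); boxcars of
the 1.5 s stimulus duration are available via `stick = FALSE`. Models 2
and 3 add, per condition, a column whose impulses are weighted by the
per-trial modulator (SCR or PDR AUC) mean-centered *within condition*, so
the modulated column is orthogonal to its condition's loading before
convolution; both the unmodulated and modulated regressors are retained,
the standard parametric-modulation construction where the published wording
is ambiguous. The design further carries six motion parameters, a
discrete-cosine high-pass set for periods above 128 s, and an intercept.

Serial correlation is handled by AR(1) prewhitening with a single
coefficient pooled over the analysis mask. The raw lag-1 autocorrelation of
OLS residuals is biased toward zero by the projection onto the design; the
estimate is debiased by adding back the white-noise expectation of that
artefactual autocorrelation, $-\mathrm{tr}(AH)/(n - p)$, computable exactly
from the hat matrix. On simulated AR(1) noise with $\rho = 0.4$ at 216
volumes the pooled estimate lands within ±0.05, and the voxel-level false
positive rate at p < 0.005 is within three binomial standard errors of
nominal on 10,000 null voxels. Passing `ar1_rho = 0` reproduces plain OLS
exactly. A per-voxel AR(1) option was considered and omitted: at 216
volumes a voxel-wise $\hat\rho$ is noisy enough to cost calibration, and
the pooled estimator is the behaviour of the major analysis packages.

The interference contrast is IC − CC on the main-effect columns (model 1)
or on the modulator columns (models 2/3). The second level is the paired
t-test across subjects on first-level (IC − CC) estimates — the exact
equivalence of a within-subject two-level condition factor. Cluster
thresholding labels supra-threshold voxels (t above the p < 0.005 quantile)
by 26-connectivity; with `extent = "auto"` the extent threshold is the
expected supra-threshold cluster size estimated by seeded sign-flip
permutations of the subject difference maps (default 1000 flips). This is
an assumption-light, deterministic stand-in for parametric expected-cluster
-size machinery; a fixed integer extent is accepted wherever a specific k
should be reproduced. Smoothing is a separable Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm, edge-renormalized
so constants are preserved.

## What the generator emulates — and what it does not

`simulate_session()` produces, from one seeded `ground_truth`:

* a pseudorandomized event design (default 18 + 18 trials of 1.5 s at a
  10.5 s inter-stimulus interval with Gaussian onset jitter, SD 0.5 s —
  the jitter law is a generator parameter because published designs often
  state only that jitter was used), with reaction times drawn at condition
  means of 1.036 s (CC) and 1.223 s (IC);
* PPG with pulses at hidden beat times (65 bpm, 30 ms interval jitter),
  amplitude-modulated sinusoidal respiration (15 breaths/min), and skin
  conductance as tonic drift plus a bi-exponential SCR kernel per event
  (rise τ 0.75 s, decay τ 2 s, latency 1.5 s — canonical SCR constants,
  all arguments);
* pupil diameter as baseline × (1 + amplitude × gamma kernel peaking 1 s
  post-onset), with condition amplitudes defaulting to 0.135 (CC) and
  0.159 (IC) of baseline and Poisson blinks flagged invalid;
* BOLD whose contamination is *phase-locked to the hidden ground truth* and
  therefore lies exactly in the span of the nuisance model, so correction
  quality is quantifiable: noiseless sessions lose ≥ 99% of contamination
  variance at every contaminated voxel, and with thermal noise the masked
  mean tSNR increases for every seed in a 10-seed suite.

The default test grid is 20 × 20 × 20 voxels (most tests use smaller grids
of a few hundred voxels with the full 216-volume time axis) so that
complete 216-volume analyses run in seconds. The generator does not emulate
k-space physics, susceptibility artifacts, head-motion image displacement
(motion parameters are nuisance covariates only; realignment is out of
scope), slow scanner drifts beyond what the high-pass removes, or
spatially correlated noise. Consequently, passing tests demonstrate the
*estimators* are correct and calibrated under the stated noise model; they
do not certify performance against artifact classes the generator does not
produce, and published real-data values (e.g. a mean brainstem tSNR of
about 68 after full preprocessing) are context, not test targets.

## Numerical choices and degenerate inputs

* Sample (n − 1) SD everywhere, fixed for reproducibility; zero-SD voxels
  in tSNR maps are `NA` plus a `defined` flag, never silently 0.
* Rank-deficient slice designs drop collinear columns with a warning;
  rank-deficient GLM designs are flagged.
* Constant modulators center to all-zero columns (flagged), infinite t
  statistics from zero-variance paired differences are reported with a
  `degenerate` flag, and an all-invalid pupil trace is an error.
* Voxel bookkeeping is 1-based with the slice axis on the third array
  dimension (configurable at generation); cluster peak coordinates are
  reported in mm as (index − 1) × voxel size.
* Every stochastic stage derives an independent stream from the master
  seed, so identical ground truth yields byte-identical sessions and
  pipeline reruns are byte-identical.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 5, n_volumes = 80,
                                    grid = c(8, 8, 4), n_per_condition = 5))
mask_summary(res$tsnr_corrected)$mean - mask_summary(res$tsnr_uncorrected)$mean
res$clusters
autoplot(res$responses_pupil)
```

The pipeline manifest records all seven stages (simulate, physio, correct,
tsnr, responses, glm, report), the seed, and the package version, and all
outputs can be written as NIfTI-1 / BIDS-style TSV via `output_dir`.
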