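Package: physiofmri
Title: Physiologically Informed Brainstem fMRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiological noise correction and physiologically informed
    statistical analysis for brainstem and midbrain fMRI. Preprocesses
    peripheral recordings (photoplethysmogram, respiration, skin conductance,
    pupil diameter), derives cardiac and respiratory phases and respiration
    volume per time (RVT), builds slice-wise RETROICOR plus RVT nuisance
    regressor sets and removes them from voxel time series, maps temporal
    signal-to-noise ratio, quantifies event-related pupil and electrodermal
    responses around task stimuli, and fits first- and second-level general
    linear models with optional parametric modulation by autonomic response
    amplitudes, including cluster-extent thresholding and atlas-mask overlap.
    A synthetic-session generator with known ground truth supports end-to-end
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
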