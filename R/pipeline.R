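#' Default pipeline configuration
#'
#' Every tunable analysis parameter in one list: scan geometry, discards,
#' nuisance-model settings, smoothing, GLM model and thresholds, and the
#' master seed. Unknown keys passed to [run_pipeline()] are rejected.
#'
#' @param ... overrides for the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_volumes = 220L, tr_s = 2.04, grid = c(20L, 20L, 20L),
    n_per_condition = 18L,
    n_discard = 4L,
    retroicor_order = 2L, rvt_lags_s = c(0, 5, 10, 15, 20),
    fwhm_mm = 4, hp_cutoff_s = 128,
    model = 1L, modulator = "none",
    voxel_p = 0.005, extent = 1L,
    noise_sd = 1, output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  if (cfg$model %in% c(2L, 3L) && cfg$modulator == "none") {
    abort(sprintf("model %d requires a modulator ('scr' for model 2, 'pdr' for model 3)",
                  cfg$model))
  }
  if (cfg$model == 2L && cfg$modulator != "scr") {
    abort("model 2 is the SCR-modulated model; set modulator = 'scr'")
  }
  if (cfg$model == 3L && cfg$modulator != "pdr") {
    abort("model 3 is the PDR-modulated model; set modulator = 'pdr'")
  }
  if (cfg$model == 1L && cfg$modulator != "none") {
    abort("model 1 takes no modulator")
  }
  invisible(cfg)
}

#' Run the simulate-then-analyze pipeline end to end
#'
#' Stages: (1) simulate a synthetic session; (2) preprocess the peripheral
#' recordings and synchronize everything to the retained scan; (3) build the
#' slice-wise nuisance set and residualize the BOLD series; (4) map tSNR
#' before/after correction; (5) extract event-related pupil and SC
#' responses; (6) fit the first-level GLM (with parametric modulation for
#' models 2/3) and compute the interference contrast; (7) assemble a run
#' manifest. Deterministic given the seed. Validation failures (e.g. model 2
#' without an SCR modulator) occur before any stage runs.
#'
#' @param config a [pipeline_config()].
#' @return list with the session, cleaned recordings, nuisance set,
#'   corrected image, tSNR maps and summaries, trial responses, GLM result,
#'   contrast maps, and a `manifest` tibble listing the stages run.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .validate_config(config)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  truth <- ground_truth(seed = cfg$seed, noise_sd = cfg$noise_sd)
  session <- simulate_session(truth, n_volumes = cfg$n_volumes,
                              tr_s = cfg$tr_s, grid = cfg$grid,
                              n_per_condition = cfg$n_per_condition)
  note("simulate")

  physio <- sync_to_scan(session$physio, cfg$n_volumes, cfg$tr_s,
                         n_discard = cfg$n_discard)
  pupil_raw <- sync_to_scan(session$pupil, cfg$n_volumes, cfg$tr_s,
                            n_discard = cfg$n_discard)
  pupil <- preprocess_pupil(pupil_raw)
  sc_clean <- preprocess_sc(physio$data$sc, physio$fs)
  events <- sync_events_to_scan(session$events, cfg$tr_s,
                                n_discard = cfg$n_discard)
  note("physio")

  bold <- discard_initial_volumes(session$bold, cfg$n_discard)
  nuis <- build_slicewise_nuisance(physio, bold$slice_times,
                                   n_volumes(bold), cfg$tr_s,
                                   retroicor_order = cfg$retroicor_order,
                                   rvt_lags_s = cfg$rvt_lags_s)
  corrected <- residualize(bold, nuis)
  note("correct")

  tsnr_un <- tsnr_map(bold, provenance = "uncorrected")
  tsnr_co <- tsnr_map(corrected, provenance = "corrected")
  tsnr_delta <- tsnr_change(tsnr_co, tsnr_un)
  note("tsnr")

  resp_pupil <- extract_trial_responses(pupil$data$pd, pupil$fs, events,
                                        channel = "pupil",
                                        time = pupil$data$time)
  resp_sc <- extract_trial_responses(sc_clean, physio$fs, events,
                                     channel = "sc",
                                     time = physio$data$time)
  note("responses")

  modulator <- switch(cfg$modulator,
                      none = NULL,
                      scr = resp_sc$auc[order(resp_sc$trial_index)],
                      pdr = resp_pupil$auc[order(resp_pupil$trial_index)])
  smoothed <- gaussian_smooth(corrected, fwhm_mm = cfg$fwhm_mm)
  motion <- session$motion[(cfg$n_discard + 1L):cfg$n_volumes, ]
  design <- build_design(events, n_volumes(bold), cfg$tr_s,
                         model = cfg$model, modulator = modulator,
                         motion = motion, hp_cutoff_s = cfg$hp_cutoff_s)
  fit <- fit_first_level(smoothed, design)
  contrast <- interference_contrast(fit)
  clusters <- cluster_threshold(contrast$t, df = contrast$df,
                                voxel_p = cfg$voxel_p, extent = cfg$extent,
                                voxel_dim_mm = bold$voxel_dim_mm)
  note("glm")

  manifest <- tibble::tibble(
    stage = c(stages, "report"),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("physiofmri"))
  )
  note("report")

  out <- list(config = cfg, session = session, physio = physio,
              pupil = pupil, sc_clean = sc_clean, events = events,
              nuisance = nuis, corrected = corrected,
              tsnr_uncorrected = tsnr_un, tsnr_corrected = tsnr_co,
              tsnr_change = tsnr_delta,
              responses_pupil = resp_pupil, responses_sc = resp_sc,
              design = design, fit = fit, contrast = contrast,
              clusters = clusters, manifest = manifest)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(session, file.path(cfg$output_dir, "session"))
    write_nuisance_tsv(nuis, file.path(cfg$output_dir, "nuisance"))
    write_map_nifti(tsnr_co, file.path(cfg$output_dir, "tsnr_corrected.nii.gz"))
    write_map_nifti(contrast$t, file.path(cfg$output_dir, "interference_t.nii.gz"),
                    voxel_dim_mm = bold$voxel_dim_mm)
    readr::write_tsv(clusters, file.path(cfg$output_dir, "clusters.tsv"))
    jsonlite::write_json(
      list(stages = manifest$stage, seed = cfg$seed,
           parameters = cfg[setdiff(names(cfg), "output_dir")]),
      file.path(cfg$output_dir, "manifest.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
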