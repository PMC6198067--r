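# Small session builders shared across test files. Grids are deliberately
# tiny so full 216-volume analyses run in seconds.

quiet_session <- function(seed = 1, ...) {
  truth <- ground_truth(seed = seed, ...)
  suppressWarnings(
    simulate_session(truth, n_volumes = 220, grid = c(6, 6, 4),
                     n_per_condition = 18)
  )
}

# Synchronize a session's pieces to the retained scan (discard 4 volumes).
sync_session <- function(sess, tr_s = 2.04, n_discard = 4) {
  list(
    bold = discard_initial_volumes(sess$bold, n_discard),
    physio = suppressWarnings(sync_to_scan(sess$physio, n_volumes(sess$bold),
                                           tr_s, n_discard)),
    pupil = suppressWarnings(sync_to_scan(sess$pupil, n_volumes(sess$bold),
                                          tr_s, n_discard)),
    events = suppressWarnings(sync_events_to_scan(sess$events, tr_s, n_discard))
  )
}

# Per-voxel temporal variances of a bold image.
voxel_variances <- function(bold) {
  d <- dim(bold$data)
  apply(matrix(bold$data, prod(d[1:3]), d[4]), 1, var)
}
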