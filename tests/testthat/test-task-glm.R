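test_that("canonical HRF has the expected shape", {
  expect_equal(canonical_hrf(0), 0)
  g <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(g)
  expect_equal(max(h), 1, tolerance = 1e-6)
  peak_t <- g[which.max(h)]
  expect_true(peak_t >= 4 && peak_t <= 6)
  expect_gt(sum(h) * 0.01, 0)          # net positive integral
  expect_lt(min(h[g > 10 & g < 25]), 0) # undershoot
  expect_equal(canonical_hrf(-1), 0)
})

test_that("design matrices have the documented column structure", {
  ev <- gen_event_design(18, seed = 61)
  motion <- gen_motion(216, seed = 61)
  des <- build_design(ev, 216, 2.04, model = 1, motion = motion)
  n_dct <- floor(2 * 216 * 2.04 / 128)
  expect_equal(des$column_names,
               c("CC", "IC", names(motion), paste0("dct", seq_len(n_dct)),
                 "intercept"))
  expect_false(des$rank_deficient)
  # models 2/3 insert mean-centered modulator columns per condition
  mod <- rnorm(36)
  des2 <- build_design(ev, 216, 2.04, model = 2, modulator = mod)
  expect_true(all(c("CC_mod", "IC_mod") %in% des2$column_names))
  expect_error(build_design(ev, 216, 2.04, model = 2), "modulator")
  expect_error(build_design(ev, 216, 2.04, model = 2, modulator = mod[1:5]),
               "36 trials")
  expect_error(build_design(ev, 216, 2.04, model = 1, modulator = mod),
               "does not accept")
})

test_that("modulator columns are centered, linear, and degenerate when constant", {
  ev <- gen_event_design(10, seed = 62)
  mod <- runif(20, 1, 3)
  d1 <- build_design(ev, 120, 2.04, model = 3, modulator = mod)
  d2 <- build_design(ev, 120, 2.04, model = 3, modulator = 2 * mod)
  i <- match(c("CC_mod", "IC_mod"), d1$column_names)
  expect_equal(2 * d1$values[, i], d2$values[, i], tolerance = 1e-10)
  expect_warning(
    dd <- build_design(ev, 120, 2.04, model = 3, modulator = rep(1, 20)),
    "rank deficient")
  expect_true(all(dd$values[, match("CC_mod", dd$column_names)] == 0))
  expect_true(dd$rank_deficient)
})

test_that("noiseless task sessions are recovered exactly by the GLM", {
  truth <- ground_truth(seed = 63, noise_sd = 0, cardiac_gain = 0,
                        resp_gain = 0, rvt_gain = 0, beta_cc = 1, beta_ic = 2)
  sess <- suppressWarnings(
    simulate_session(truth, n_volumes = 220, grid = c(5, 5, 2),
                     n_per_condition = 18))
  sy <- sync_session(sess)
  des <- build_design(sy$events, n_volumes(sy$bold), 2.04, model = 1)
  fit <- fit_first_level(sy$bold, des)
  con <- interference_contrast(fit)
  act <- sess$truth$active_voxel_set
  expect_lt(max(abs(con$contrast[act] - 1)), 1e-6)
  # the active-voxel t values dominate all others
  expect_gt(min(con$t[act], na.rm = TRUE),
            max(con$t[-act], -Inf, na.rm = TRUE))
})

test_that("whitening with rho = 0 reproduces the plain OLS fit", {
  set.seed(64)
  ev <- gen_event_design(6, seed = 64)
  n <- 80
  arr <- array(rnorm(4 * n), dim = c(2, 2, 1, n))
  des <- build_design(ev, n, 2.04, model = 1)
  fit0 <- fit_first_level(bold_image(arr, tr_s = 2.04), des, ar1_rho = 0)
  for (v in 1:4) {
    ij <- arrayInd(v, c(2, 2))
    y <- arr[ij[1], ij[2], 1, ]
    expect_equal(unname(fit0$betas[, v]),
                 unname(coef(lm(y ~ des$values - 1))), tolerance = 1e-8)
  }
})

test_that("pooled AR(1) estimate is consistent at rho = 0.4", {
  ev <- gen_event_design(18, seed = 65)
  des <- build_design(ev, 216, 2.04, model = 1)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    m <- replicate(40, as.numeric(arima.sim(list(ar = 0.4), 216)))
    fit_first_level(bold_image(array(t(m), dim = c(40, 1, 1, 216)),
                               tr_s = 2.04), des)$ar1_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.4), 0.05)
})

test_that("contrast maps negate under condition-label exchange", {
  truth <- ground_truth(seed = 66, cardiac_gain = 0, resp_gain = 0,
                        rvt_gain = 0)
  sess <- suppressWarnings(
    simulate_session(truth, n_volumes = 100, grid = c(4, 4, 2),
                     n_per_condition = 8))
  sy <- sync_session(sess)
  ev_sw <- sy$events
  ev_sw$trial_type <- ifelse(ev_sw$trial_type == "CC", "IC", "CC")
  fit_a <- fit_first_level(sy$bold, build_design(sy$events, n_volumes(sy$bold),
                                                 2.04, model = 1))
  fit_b <- fit_first_level(sy$bold, build_design(ev_sw, n_volumes(sy$bold),
                                                 2.04, model = 1))
  ca <- interference_contrast(fit_a)
  cb <- interference_contrast(fit_b)
  expect_equal(ca$contrast, -cb$contrast, tolerance = 1e-10)
})

test_that("voxel-level type-I error is nominal on null data", {
  set.seed(67)
  ev <- gen_event_design(18, seed = 67)
  n <- 216
  arr <- array(rnorm(10000 * n), dim = c(100, 100, 1, n))
  fit <- fit_first_level(bold_image(arr, tr_s = 2.04),
                         build_design(ev, n, 2.04, model = 1))
  con <- interference_contrast(fit)
  rate <- mean(con$t > qt(1 - 0.005, con$df))
  expect_lt(abs(rate - 0.005), 3 * sqrt(0.005 * 0.995 / 10000))
})

test_that("second-level paired t matches its textbook oracle voxel-wise", {
  set.seed(68)
  grid <- c(4, 4, 3)
  n <- 11
  cc <- lapply(1:n, function(i) array(rnorm(prod(grid)), grid))
  ic <- lapply(1:n, function(i) array(rnorm(prod(grid), 0.5), grid))
  res <- second_level_paired(cc, ic)
  expect_equal(res$df, n - 1)
  for (v in sample(prod(grid), 10)) {
    d <- vapply(1:n, function(i) ic[[i]][v] - cc[[i]][v], numeric(1))
    expect_equal(res$t[v], mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-10)
  }
  expect_equal(second_level_paired(cc, cc)$t, array(0, grid))
  expect_error(second_level_paired(cc[1:2], ic[1:2]), "at least 3")
  expect_error(second_level_paired(cc, ic[1:5]), "subject counts differ")
})

test_that("group effects at active voxels are detected across seeds", {
  grid <- c(8, 8, 4)
  act <- array(FALSE, grid); act[4:5, 4:5, 2:3] <- TRUE
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    cc <- lapply(1:11, function(i) array(rnorm(prod(grid)), grid))
    # per-subject paired difference of effect size d = 1.5 at active voxels
    ic <- lapply(cc, function(m) m + array(rnorm(prod(grid), ifelse(act, 1.5, 0)), grid))
    res <- second_level_paired(cc, ic)
    mean(res$t[act] > qt(0.995, res$df)) > 0.5
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("cluster extent rules retain and reject whole blobs", {
  grid <- c(10, 10, 5)
  tmap <- array(0, grid)
  blob <- array(FALSE, grid); blob[3:7, 3:8, 2] <- TRUE # 30 voxels
  tmap[blob] <- 5
  tab <- cluster_threshold(tmap, df = 10, voxel_p = 0.005, extent = 12)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size_voxels, 30)
  expect_equal(tab$peak_t, 5)
  tab2 <- cluster_threshold(tmap, df = 10, voxel_p = 0.005, extent = 31)
  expect_equal(nrow(tab2), 0)
  tab3 <- cluster_threshold(array(0, grid), df = 10, extent = 1)
  expect_equal(nrow(tab3), 0)
  expect_error(cluster_threshold(tmap, df = 10, extent = "auto"),
               "second_level_result")
})

# independent oracle: iterative minimum-label propagation over 26-neighbours
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    changed <- FALSE
    for (v in which(mask)) {
      co <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      ni <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
      ni <- ni[mask[ni]]
      m <- min(lab[v], lab[ni])
      if (m < lab[v]) { lab[v] <- m; changed <- TRUE }
      if (any(lab[ni] > m)) { lab[ni][lab[ni] > m] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

test_that("connected-component labeling agrees with a flood-fill oracle", {
  set.seed(69)
  for (i in 1:50) {
    mask <- array(runif(6 * 6 * 4) < 0.25, dim = c(6, 6, 4))
    lab <- physiofmri:::label_components(mask)
    oracle <- flood_fill_oracle(mask)
    # same partition: cluster memberships must match up to relabeling
    expect_equal(sort(tabulate(lab[lab > 0])),
                 sort(as.integer(table(oracle[oracle > 0]))))
    key <- paste(lab[mask], oracle[mask])
    expect_equal(length(unique(key)), length(unique(lab[lab > 0])))
  }
})

test_that("permutation-estimated extent thresholds are deterministic and sane", {
  set.seed(70)
  grid <- c(8, 8, 4)
  act <- array(FALSE, grid); act[4:6, 4:6, 2:3] <- TRUE
  cc <- lapply(1:11, function(i) array(rnorm(prod(grid)), grid))
  ic <- lapply(1:11, function(i) array(rnorm(prod(grid)) + ifelse(act, 1.5, 0), grid))
  res <- second_level_paired(cc, ic)
  t1 <- cluster_threshold(res, extent = "auto", n_permutations = 100, seed = 3)
  t2 <- cluster_threshold(res, extent = "auto", n_permutations = 100, seed = 3)
  expect_identical(t1, t2)
  expect_gte(attr(t1, "threshold")$extent_k, 1)
})

test_that("atlas overlap counts cluster voxels inside the mask", {
  grid <- c(6, 6, 3)
  mask <- array(FALSE, grid); mask[1:3, , ] <- TRUE
  inside <- which(mask)[1:5]
  outside <- which(!mask)[1:5]
  expect_equal(atlas_overlap(inside, mask)$fraction, 1)
  expect_equal(atlas_overlap(outside, mask)$fraction, 0)
  half <- atlas_overlap(c(inside, outside), mask)
  expect_equal(half$n_overlap, 5)
  expect_equal(half$fraction, 0.5)
  clus <- array(FALSE, grid); clus[3:4, 1, 1] <- TRUE
  expect_equal(atlas_overlap(clus, mask)$fraction, 0.5)
  expect_error(atlas_overlap(array(TRUE, c(2, 2, 2)), mask), "different grids")
})

test_that("Gaussian smoothing conserves mass and leaves constants unchanged", {
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 1.699, tolerance = 1e-3)
  const <- array(7, dim = c(8, 8, 6))
  expect_equal(gaussian_smooth(const, 4, voxel_dim_mm = c(1.5, 1.5, 1.5)),
               const, tolerance = 1e-10)
  delta <- array(0, dim = c(21, 21, 21)); delta[11, 11, 11] <- 1
  sm <- gaussian_smooth(delta, 4, voxel_dim_mm = c(1.5, 1.5, 1.5))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_lt(max(sm), 1)
})

test_that("tidy and glance summarize first-level fits", {
  truth <- ground_truth(seed = 71)
  sess <- suppressWarnings(
    simulate_session(truth, n_volumes = 60, grid = c(4, 4, 2),
                     n_per_condition = 4))
  sy <- sync_session(sess)
  fit <- fit_first_level(sy$bold, build_design(sy$events, n_volumes(sy$bold),
                                               2.04, model = 1))
  td <- tidy(fit)
  expect_true(all(c("term", "mean_estimate", "sd_estimate") %in% names(td)))
  expect_equal(nrow(td), ncol(fit$design$values))
  gl <- glance(fit)
  expect_equal(gl$n_voxels, 32)
  expect_true(is.finite(gl$ar1_rho))
})
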