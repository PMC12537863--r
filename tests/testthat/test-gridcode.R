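# angles-only grid-search oracle for the orientation implied by mean
# quadrature betas: the signal ms*sin(k a) + mc*cos(k a) equals
# R*cos(k*(a - phi*)); find phi* by maximizing the overlap on a fine grid
orientation_oracle <- function(ms, mc, k) {
  grid <- seq(0, 360 / k, by = 0.005)
  a <- seq(0, 359, by = 1)
  target <- ms * sin(k * a * pi / 180) + mc * cos(k * a * pi / 180)
  score <- vapply(grid, function(phi)
    sum(target * cos(k * (a - phi) * pi / 180)), 0)
  grid[which.max(score)]
}

test_that("split halves are contiguous, exhaustive, and reversible", {
  sub <- fixture_subject()
  sp <- split_halves(sub$saccades, sub$trials, "forward")
  n_tr <- nrow(sub$trials)
  expect_identical(sort(c(sp$estimation_trials, sp$test_trials)),
                   sort(sub$trials$trial_id))
  expect_identical(length(sp$estimation_trials), as.integer(ceiling(n_tr / 2)))
  expect_lt(max(sub$trials$onset_ms[sub$trials$trial_id %in%
                                      sp$estimation_trials]),
            min(sub$trials$onset_ms[sub$trials$trial_id %in% sp$test_trials]))
  rev <- split_halves(sub$saccades, sub$trials, "reversed")
  expect_identical(rev$estimation_trials, sp$test_trials)
  expect_identical(rev$test_trials, sp$estimation_trials)
  expect_identical(nrow(sp$estimation) + nrow(sp$test), nrow(sub$saccades))
  # a half under the 30-saccade floor is rejected
  few <- sub$saccades[seq_len(45), ]
  expect_error(split_halves(few, sub$trials, "forward"), "fewer than 30")
})

test_that("orientation recovery is quadrant-aware and matches the oracle", {
  cases <- list(c(0, 1, 0), c(1, 1, 7.5), c(-1, -1, 37.5), c(1, -1, 22.5),
                c(-1, 1, 52.5))
  for (cs in cases) {
    phi <- orientation_from_betas(list(beta_sin = cs[1], beta_cos = cs[2]),
                                  k = 6)
    expect_equal(phi$phi_deg, cs[3], tolerance = 1e-10)
    expect_equal(phi$phi_deg, orientation_oracle(cs[1], cs[2], 6),
                 tolerance = 0.01)
  }
  expect_error(orientation_from_betas(list(beta_sin = 0, beta_cos = 0), 6),
               "both zero")
})

test_that("quadrature betas encode the true phase (noiseless)", {
  cfg <- noiseless_config(seed = 50, true_orientation_deg = 33)
  sub <- simulate_subject(cfg, detect = FALSE)
  sp <- split_halves(sub$saccades, sub$trials, "forward")
  roi <- generate_roi_bold(sp$estimation, cfg, n_scans = sub$n_scans)
  qb <- estimate_quadrature(roi$bold, sp$estimation, sp$test, NULL, 6,
                            cfg$tr_s)
  # beta_sin/beta_cos = tan(k * phi0)
  expect_equal(mean(qb$beta_sin) / mean(qb$beta_cos),
               tan(6 * 33 * pi / 180), tolerance = 1e-6)
  # amplitude identity: a*cos(k(a-phi0)) decomposes with coefficient a
  expect_equal(sqrt(mean(qb$beta_sin)^2 + mean(qb$beta_cos)^2),
               cfg$modulation_amplitude, tolerance = 1e-6)
  # zero-amplitude signal leaves no directional structure
  cfg0 <- noiseless_config(seed = 50, modulation_amplitude = 0,
                           true_orientation_deg = 33)
  roi0 <- generate_roi_bold(sp$estimation, cfg0, n_scans = sub$n_scans)
  qb0 <- estimate_quadrature(roi0$bold, sp$estimation, sp$test, NULL, 6,
                             cfg0$tr_s)
  expect_lt(max(abs(c(qb0$beta_sin, qb0$beta_cos))), 1e-10)
  # permuting saccade order changes nothing
  perm <- sp$estimation[sample.int(nrow(sp$estimation)), ]
  qbp <- estimate_quadrature(roi$bold, perm, sp$test, NULL, 6, cfg$tr_s)
  expect_equal(qbp$beta_sin, qb$beta_sin, tolerance = 1e-12)
})

test_that("alignment testing recovers amplitude, sign, and equivariance", {
  cfg <- noiseless_config(seed = 51, true_orientation_deg = 12)
  sub <- simulate_subject(cfg, detect = FALSE)
  sp <- split_halves(sub$saccades, sub$trials, "forward")
  roi <- generate_roi_bold(sp$test, cfg, n_scans = sub$n_scans)
  aligned <- test_alignment(roi$bold, sp$test, sp$estimation, 12, NULL, 6,
                            cfg$tr_s)
  expect_equal(aligned$value, cfg$modulation_amplitude, tolerance = 1e-6)
  # a phase error of half the period flips the sign exactly
  flipped <- test_alignment(roi$bold, sp$test, sp$estimation, 12 + 30, NULL,
                            6, cfg$tr_s)
  expect_equal(flipped$value, -aligned$value, tolerance = 1e-6)
  # periodicity: phi + 60 is the same orientation
  per <- test_alignment(roi$bold, sp$test, sp$estimation, 12 + 60, NULL, 6,
                        cfg$tr_s)
  expect_equal(per$value, aligned$value, tolerance = 1e-9)
  # rotational equivariance: rotating all angles by delta shifts phi-hat
  # and leaves the aligned magnitude unchanged
  delta <- 14
  rot <- function(df) { df$direction_deg <- (df$direction_deg + delta) %% 360; df }
  cfg_rot <- cfg
  sub_rot <- sub
  sub_rot$saccades <- rot(sub$saccades)
  sp_rot <- split_halves(sub_rot$saccades, sub$trials, "forward")
  roi_est <- generate_roi_bold(sp$estimation, cfg, n_scans = sub$n_scans)
  qb <- estimate_quadrature(roi_est$bold, sp$estimation, sp$test, NULL, 6,
                            cfg$tr_s)
  phi_hat <- orientation_from_betas(qb)$phi_deg
  # rotated world: regenerate estimation-half BOLD from rotated angles with
  # rotated true orientation
  cfg_rot$true_orientation_deg <- (12 + delta) %% 60
  roi_est_rot <- generate_roi_bold(sp_rot$estimation, cfg_rot,
                                   n_scans = sub$n_scans)
  qb_rot <- estimate_quadrature(roi_est_rot$bold, sp_rot$estimation,
                                sp_rot$test, NULL, 6, cfg$tr_s)
  phi_rot <- orientation_from_betas(qb_rot)$phi_deg
  expect_equal(gridgaze:::circ_diff_deg(phi_rot, phi_hat + delta, 60), 0,
               tolerance = 1e-6)
  roi_rot <- generate_roi_bold(sp_rot$test, cfg_rot, n_scans = sub$n_scans)
  aligned_rot <- test_alignment(roi_rot$bold, sp_rot$test, sp_rot$estimation,
                                phi_rot, NULL, 6, cfg$tr_s)
  expect_equal(aligned_rot$value, cfg$modulation_amplitude, tolerance = 1e-6)
})

test_that("estimation and test halves are independent", {
  cfg <- noiseless_config(seed = 52)
  sub <- simulate_subject(cfg, detect = FALSE)
  sp <- split_halves(sub$saccades, sub$trials, "forward")
  roi <- generate_roi_bold(sub$saccades, cfg, n_scans = sub$n_scans)
  qb <- estimate_quadrature(roi$bold, sp$estimation, sp$test, NULL, 6,
                            cfg$tr_s)
  phi <- orientation_from_betas(qb)$phi_deg
  # shuffling the test half's angles cannot move the estimate ...
  shuf <- sp$test
  set.seed(99)
  shuf$direction_deg <- sample(shuf$direction_deg)
  qb2 <- estimate_quadrature(roi$bold, sp$estimation, shuf, NULL, 6,
                             cfg$tr_s)
  expect_equal(orientation_from_betas(qb2)$phi_deg, phi, tolerance = 1e-9)
  # ... but destroys the held-out alignment
  mag_true <- test_alignment(roi$bold, sp$test, sp$estimation, phi, NULL, 6,
                             cfg$tr_s)$value
  mag_shuf <- test_alignment(roi$bold, shuf, sp$estimation, phi, NULL, 6,
                             cfg$tr_s)$value
  expect_gt(mag_true, 0.4)
  expect_lt(abs(mag_shuf), 0.15)
})

test_that("the orchestrated analysis covers folds, orders, and conditions", {
  sub <- fixture_subject()
  g <- grid_analysis(sub, folds = c(5L, 6L), orders = c("forward", "reversed"),
                     conditions = "all")
  expect_identical(nrow(g), 4L)
  expect_setequal(unique(g$k), c(5L, 6L))
  expect_true(all(g$phi_deg >= 0 & g$phi_deg < 360 / g$k))
  # condition-specific testing keeps estimation on all trials: the
  # orientation must match the unconditional run
  if (sum(sub$trials$memory == "hit", na.rm = TRUE) > 10) {
    gh <- grid_analysis(sub, folds = 6L, orders = "forward",
                        conditions = c("all", "hits"), min_saccades = 10L)
    expect_equal(gh$phi_deg[gh$condition == "hits"],
                 gh$phi_deg[gh$condition == "all"])
  }
  # too few condition saccades is an error
  sp <- split_halves(sub$saccades, sub$trials, "forward")
  one_trial <- sp$test_trials[1]
  expect_error(test_alignment(sub$bold, sp$test, sp$estimation, 10,
                              sub$motion, 6, sub$tr_s,
                              condition_trials = one_trial),
               "minimum")
})

test_that("trial-wise magnitudes are bounded means of per-saccade cosines", {
  sac <- data.frame(trial_id = c(1, 1, 2, 2, 3),
                    direction_deg = c(20, 20, 20, 50, 110))
  tw <- trialwise_magnitudes(sac, phi = 20, k = 6)
  expect_equal(tw$value[tw$trial_id == 1], 1)           # all aligned
  expect_equal(tw$value[tw$trial_id == 2], 0, tolerance = 1e-12) # 0 and 180 deg phase
  expect_true(all(abs(tw$value) <= 1))
  # a trial with no saccades is flagged missing
  tw2 <- trialwise_magnitudes(sac, 20, 6, trial_ids = 1:4)
  expect_true(is.na(tw2$value[tw2$trial_id == 4]))
  # many uniform angles average toward zero
  set.seed(13)
  big <- data.frame(trial_id = 1, direction_deg = runif(20000, 0, 360))
  expect_lt(abs(trialwise_magnitudes(big, 20, 6)$value), 0.02)
  # both partition orders together cover every trial
  sub <- fixture_subject()
  ser <- grid_trial_series(sub, k = 6)
  expect_setequal(ser$trial_id, sub$trials$trial_id)
  expect_true(all(abs(ser$value[!is.na(ser$value)]) <= 1))
})

test_that("trial-modulation GLM recovers an injected coefficient", {
  sub <- fixture_subject()
  ser <- grid_trial_series(sub, k = 6)
  # synthesize a voxel whose trial amplitude tracks the series with slope c
  cc <- 1.7
  hrf <- canonical_hrf(sub$tr_s)
  v <- ser$value[match(sub$trials$trial_id, ser$trial_id)]
  keep <- !is.na(v)
  reg <- build_regressor(
    event_list(sub$trials$onset_s[keep], sub$trials$duration_s[keep],
               v[keep], "scene"), sub$n_scans, sub$tr_s, hrf)
  set.seed(14)
  y <- 5 + cc * reg[, "scene_pmod"] + 0.8 * reg[, "scene"] +
    rnorm(sub$n_scans, 0, 0.05)
  fit <- build_trial_parametric_design(cbind(y), sub$trials[keep, ], ser,
                                       NULL, sub$tr_s)
  expect_equal(unname(fit$beta[1]), cc, tolerance = 0.1)
  # permuting trials with their values leaves the fit unchanged
  perm <- sample(which(keep))
  fit_p <- build_trial_parametric_design(cbind(y), sub$trials[perm, ], ser,
                                         NULL, sub$tr_s)
  expect_equal(unname(fit_p$beta[1]), unname(fit$beta[1]), tolerance = 1e-10)
  # constant series: the centered modulator collapses
  const <- ser
  const$value <- 0.5
  expect_error(build_trial_parametric_design(cbind(y), sub$trials[keep, ],
                                             const, NULL, sub$tr_s),
               "constant trial series")
})
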