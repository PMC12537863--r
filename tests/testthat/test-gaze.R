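make_recording <- function(x, y, pupil = NULL, rate = 1000,
                           screen_px = c(1280, 960),
                           screen_cm = c(36.9, 27.7), dist = 86.6) {
  n <- length(x)
  if (is.null(pupil)) pupil <- rep(3000, n)
  gaze_recording((0:(n - 1)) * 1000 / rate, x, y, pupil, rate,
                 screen_px, screen_cm, dist)
}

test_that("pixel-to-degree conversion follows the screen geometry", {
  rec <- make_recording(c(640, 641, 639, 640), c(480, 480, 480, 400))
  d <- px_to_deg(rec)
  expect_equal(d$x_deg[1], 0)
  expect_equal(d$y_deg[1], 0)
  # one horizontal pixel at the Donders geometry
  expect_equal(d$x_deg[2], atan((36.9 / 1280) / 86.6) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(d$x_deg[2], 0.01907, tolerance = 1e-3)
  # odd symmetry of mirrored offsets
  expect_equal(d$x_deg[3], -d$x_deg[2])
  # y is up-positive: moving up the screen (smaller y_px) is positive
  expect_gt(d$y_deg[4], 0)
})

test_that("velocity is the central-difference norm and is reversal-invariant", {
  n <- 100
  rec <- make_recording(rep(5, n), rep(7, n))
  v <- compute_velocity(rec)
  expect_true(all(v[!is.na(v)] == 0))
  # linear ramp: 10 px/sample at 1000 Hz is 10,000 px/s
  rec2 <- make_recording(10 * (1:n), rep(0, n))
  v2 <- compute_velocity(rec2)
  expect_equal(unname(v2[10]), 10000)
  # reversing the trajectory flips the sign, not the magnitude
  rec3 <- make_recording(rev(10 * (1:n)), rep(0, n))
  expect_equal(compute_velocity(rec3), v2)
  expect_error(compute_velocity(rec, 1), "must be >= 2")
  # missing positions propagate
  xm <- 10 * (1:n); xm[50] <- NA
  vm <- compute_velocity(make_recording(xm, rep(0, n)))
  expect_true(all(is.na(vm[48:52])))
})

test_that("blink detection flags pupil deviations and merges close runs", {
  n <- 20000
  pupil <- rep(1000, n) + rep(c(-1, 1), n / 2)  # tiny variance
  rec <- make_recording(rnorm(n, 640, 1), rnorm(n, 480, 1), pupil)
  expect_identical(nrow(detect_blinks(rec)), 0L)
  # a brief dropout to zero is far beyond 5 SD of the (rare-blink) trace
  pupil2 <- pupil; pupil2[500:600] <- 0
  b <- detect_blinks(make_recording(rnorm(n, 640, 1), rnorm(n, 480, 1), pupil2))
  expect_identical(nrow(b), 1L)
  expect_lte(b$start_ms, 500)
  expect_gte(b$end_ms, 598)
  # two dropouts one sample apart are merged
  pupil3 <- pupil; pupil3[500:510] <- 0; pupil3[512:520] <- 0
  b3 <- detect_blinks(make_recording(rnorm(n, 640, 1), rnorm(n, 480, 1), pupil3))
  expect_identical(nrow(b3), 1L)
  expect_error(detect_blinks(make_recording(rnorm(n), rnorm(n),
                                            rep(NA_real_, n))),
               "entirely missing")
})

test_that("direction angles follow the y-up, 0-right convention", {
  expect_equal(compute_direction(c(0, 0), c(10, 0)), 0)
  expect_equal(compute_direction(c(0, 0), c(0, -10)), 90)  # up on screen
  expect_equal(compute_direction(c(0, 0), c(-10, 0)), 180)
  expect_equal(compute_direction(c(0, 0), c(10, 10)), 315) # down-right
  expect_error(compute_direction(c(1, 1), c(1, 1)), "zero displacement")
})

test_that("saccade detection closes the loop on injected ground truth", {
  cfg <- small_config(seed = 9, blink_prob_per_trial = 0)
  gz <- generate_gaze(cfg)
  det <- detect_saccades(gz$recording)
  sc <- saccade_detection_score(gz$truth$true_saccades, det)
  expect_gte(sc$precision, 0.95)
  expect_gte(sc$recall, 0.95)
  expect_lt(max(abs(sc$onset_errors_ms)), 5)
  # noiseless single-saccade case: exactly one detection
  cfg1 <- simulation_config(seed = 5, n_trials = 2, gaze_noise_px = 0.1,
                            saccades_per_trial_mean = 1,
                            blink_prob_per_trial = 0)
  gz1 <- generate_gaze(cfg1)
  det1 <- detect_saccades(gz1$recording)
  expect_identical(nrow(det1), nrow(gz1$truth$true_saccades))
})

test_that("retained saccades satisfy the duration and fixation rules", {
  cfg <- small_config(seed = 10)
  gz <- generate_gaze(cfg)
  p <- detection_params("donders")
  det <- detect_saccades(gz$recording, p)
  expect_true(all(det$duration_ms > p$min_saccade_duration_ms))
  expect_true(all(det$direction_deg >= 0 & det$direction_deg < 360))
  # raising the duration floor above the generator's range empties the set
  p35 <- detection_params("donders", min_saccade_duration_ms = 60)
  expect_lt(nrow(detect_saccades(gz$recording, p35)), nrow(det) * 0.1)
  # a flat, noise-free trace has no velocity variance to threshold
  flat <- make_recording(rep(640, 500), rep(480, 500))
  expect_error(detect_saccades(flat), "zero variance")
  # near-constant trace with jitter: no saccades
  jit <- make_recording(rnorm(500, 640, 0.3), rnorm(500, 480, 0.3))
  expect_identical(nrow(detect_saccades(jit)), 0L)
})

test_that("detection is invariant to translation and 90-degree rotation", {
  cfg <- simulation_config(seed = 11, n_trials = 10, screen_px = c(960, 960),
                           screen_cm = c(27.7, 27.7),
                           blink_prob_per_trial = 0)
  gz <- generate_gaze(cfg)
  rec <- gz$recording
  det <- detect_saccades(rec)
  shift <- gaze_recording(rec$time_ms, rec$x_px + 100, rec$y_px - 50,
                          rec$pupil, rec$sampling_rate_hz, rec$screen_px,
                          rec$screen_cm, rec$viewing_distance_cm)
  det_s <- detect_saccades(shift)
  expect_equal(det_s$onset_ms, det$onset_ms)
  expect_equal(det_s$direction_deg, det$direction_deg)
  # rotate pixel coordinates by 90 degrees about the screen centre
  cx <- rec$screen_px[1] / 2; cy <- rec$screen_px[2] / 2
  rot <- gaze_recording(rec$time_ms, cx - (rec$y_px - cy), cy + (rec$x_px - cx),
                        rec$pupil, rec$sampling_rate_hz, rec$screen_px,
                        rec$screen_cm, rec$viewing_distance_cm)
  det_r <- detect_saccades(rot)
  expect_equal(det_r$onset_ms, det$onset_ms)
  shift_deg <- (det_r$direction_deg - det$direction_deg) %% 360
  expect_equal(shift_deg, rep(270, nrow(det)))
})

test_that("exclusion rules mark blinks, adjacency, and bad trials", {
  sac <- data.frame(onset_ms = c(1150, 3000, 5000, 5105),
                    offset_ms = c(1180, 3030, 5030, 5135),
                    duration_ms = 30, start_x = 0, start_y = 0,
                    end_x = 10, end_y = 0, direction_deg = 0,
                    amplitude_deg = 1, peak_velocity = 500,
                    trial_id = NA_integer_, excluded_reason = "none")
  blinks <- data.frame(start_ms = 900, end_ms = 1100)
  trials <- data.frame(trial_id = 1:2, onset_ms = c(1000, 4500),
                       duration_ms = c(2500, 2000))
  n <- 8000
  rec <- make_recording(rnorm(n, 640, 1), rnorm(n, 480, 1))
  don <- detection_params("donders")
  out <- filter_saccades(sac, blinks, trials, rec, don)
  # saccade onset 50 ms after blink end with the 100 ms pad: excluded
  expect_identical(out$excluded_reason[out$onset_ms == 1150], "blink")
  expect_identical(out$excluded_reason[out$onset_ms == 3000], "none")
  # Donders has no adjacency rule; Vienna's 100 ms pad kills the close pair
  expect_true(all(out$excluded_reason[out$onset_ms >= 5000] == "none"))
  vie <- detection_params("vienna", blink_pad_ms = 100)
  out_v <- filter_saccades(sac, blinks, trials, rec, vie)
  expect_true(all(out_v$excluded_reason[out_v$onset_ms >= 5000] == "adjacent"))
  # no blinks, clean trials: identity
  clean <- filter_saccades(sac, blinks[0, ], trials, rec, don)
  expect_true(all(clean$excluded_reason == "none"))
  expect_identical(clean$trial_id, c(1L, 1L, 2L, 2L))
  # idempotence
  again <- filter_saccades(out, blinks, trials, rec, don)
  expect_identical(again$excluded_reason, out$excluded_reason)
  # a trial with > 25% missing data loses its saccades
  xm <- rnorm(n, 640, 1); xm[4500:5300] <- NA  # 40% of trial 2
  rec_m <- make_recording(xm, rnorm(n, 480, 1))
  out_m <- filter_saccades(sac, blinks[0, ], trials, rec_m, don)
  expect_true(all(out_m$excluded_reason[out_m$trial_id == 2] ==
                    "trial_missing_data"))
  # overlapping trials are rejected
  bad_tr <- data.frame(trial_id = 1:2, onset_ms = c(1000, 2000),
                       duration_ms = c(2500, 2000))
  expect_error(filter_saccades(sac, blinks, bad_tr, rec, don), "overlap")
})
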