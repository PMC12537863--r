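#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic gaze / BOLD / behavior
#' generators. Paradigm defaults follow the free-viewing recognition
#' paradigm: 200 scene trials of 4 s, inter-trial intervals of 2.125,
#' 4.125, or 7.125 s in an 80:80:40 ratio, 1000 Hz eye tracking on a
#' 1280 x 960 px screen (36.9 x 27.7 cm at 86.6 cm), and fMRI at
#' TR = 0.657 s with a 25-voxel region of interest. The directional BOLD
#' modulation has amplitude `modulation_amplitude` around orientation
#' `true_orientation_deg` with `symmetry_fold`-fold periodicity.
#'
#' @param seed Integer RNG seed; each generator derives its own stream
#'   from it, so a fixed seed makes every output bit-identical.
#' @param n_trials Number of study trials.
#' @param trial_duration_s Scene presentation time, seconds.
#' @param iti_values_s,iti_weights Inter-trial-interval values (s) and
#'   sampling weights (normalized to probabilities).
#' @param sampling_rate_hz Eye-tracker sampling rate.
#' @param tr_s fMRI repetition time, seconds.
#' @param screen_px,screen_cm,viewing_distance_cm Screen geometry.
#' @param true_orientation_deg Ground-truth grid orientation phi0 in
#'   [0, 360/k).
#' @param symmetry_fold Rotational symmetry k (4-8; 6 is the grid model).
#' @param modulation_amplitude Directional modulation amplitude a >= 0:
#'   neural impulse height is 1 + a*cos(k*(alpha - phi0)).
#' @param noise_sd Per-voxel Gaussian BOLD noise SD (signal units).
#' @param n_voxels Voxels in the simulated ROI.
#' @param saccades_per_trial_mean Mean saccades per trial (Poisson).
#' @param blink_prob_per_trial Probability of a blink in a given trial.
#' @param true_dprime,criterion Equal-variance signal-detection
#'   parameters of the behavioral model.
#' @param gaze_noise_px SD of Gaussian positional jitter during fixation.
#' @param amplitude_range_deg Saccade amplitude range, degrees.
#' @param drift_amplitude Peak-to-peak linear drift scale per voxel.
#' @param ar1_phi Optional AR(1) coefficient for the BOLD noise
#'   (0 = white, the default).
#' @param baseline Additive BOLD baseline (keeps voxel means positive for
#'   mean-intensity quality scoring).
#' @param rating_scale 6 (hits = ratings 1-3) or 4 (hits = ratings 1-2).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_trials = 200L,
                              trial_duration_s = 4,
                              iti_values_s = c(2.125, 4.125, 7.125),
                              iti_weights = c(80, 80, 40),
                              sampling_rate_hz = 1000,
                              tr_s = 0.657,
                              screen_px = c(1280, 960),
                              screen_cm = c(36.9, 27.7),
                              viewing_distance_cm = 86.6,
                              true_orientation_deg = 20,
                              symmetry_fold = 6L,
                              modulation_amplitude = 0.5,
                              noise_sd = 1,
                              n_voxels = 25L,
                              saccades_per_trial_mean = 7.58,
                              blink_prob_per_trial = 0.2,
                              true_dprime = 1.82,
                              criterion = 0.91,
                              gaze_noise_px = 0.5,
                              amplitude_range_deg = c(2, 10),
                              drift_amplitude = 0.5,
                              ar1_phi = 0,
                              baseline = 100,
                              rating_scale = 6L) {
  if (!symmetry_fold %in% 4:8) stopf("symmetry_fold must be in {4,...,8}")
  check_number(true_orientation_deg, "true_orientation_deg",
               lower = 0, upper = 360 / symmetry_fold - 1e-12)
  check_number(modulation_amplitude, "modulation_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(saccades_per_trial_mean, "saccades_per_trial_mean",
               lower = .Machine$double.eps)
  check_number(blink_prob_per_trial, "blink_prob_per_trial",
               lower = 0, upper = 1)
  check_number(gaze_noise_px, "gaze_noise_px", lower = 0)
  check_number(true_dprime, "true_dprime")
  if (length(iti_values_s) != length(iti_weights) || any(iti_weights < 0))
    stopf("iti_weights must be non-negative and match iti_values_s")
  iti_weights <- iti_weights / sum(iti_weights)
  if (!rating_scale %in% c(4L, 6L)) stopf("rating_scale must be 4 or 6")
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s,
                 iti_values_s = iti_values_s, iti_weights = iti_weights,
                 sampling_rate_hz = sampling_rate_hz, tr_s = tr_s,
                 screen_px = screen_px, screen_cm = screen_cm,
                 viewing_distance_cm = viewing_distance_cm,
                 true_orientation_deg = true_orientation_deg,
                 symmetry_fold = as.integer(symmetry_fold),
                 modulation_amplitude = modulation_amplitude,
                 noise_sd = noise_sd, n_voxels = as.integer(n_voxels),
                 saccades_per_trial_mean = saccades_per_trial_mean,
                 blink_prob_per_trial = blink_prob_per_trial,
                 true_dprime = true_dprime, criterion = criterion,
                 gaze_noise_px = gaze_noise_px,
                 amplitude_range_deg = amplitude_range_deg,
                 drift_amplitude = drift_amplitude, ar1_phi = ar1_phi,
                 baseline = baseline, rating_scale = as.integer(rating_scale)),
            class = "simulation_config")
}

# trial onset table implied by the config (deterministic ITI draw happens
# inside generate_gaze; this helper is used once the ITIs are drawn)
make_trials <- function(onsets_s, duration_s) {
  data.frame(trial_id = seq_along(onsets_s), onset_ms = onsets_s * 1000,
             duration_ms = duration_s * 1000,
             onset_s = onsets_s, duration_s = duration_s)
}

#' Generate a synthetic gaze recording with known ground truth
#'
#' Emulates trial-structured free viewing: fixations with Gaussian
#' positional jitter, saccades as raised-cosine position ramps of 20-60 ms
#' between fixation points (amplitudes uniform over
#' `amplitude_range_deg`, directions approximately uniform on [0, 360)),
#' and blinks as pupil dropouts with missing position samples. The
#' injected event lists are returned as ground truth.
#'
#' @param config A [simulation_config()].
#' @return List with `recording` (a [gaze_recording()]), `truth` (true
#'   saccades, blink intervals, trial table, `true_orientation_deg`), and
#'   `trials`.
#' @export
generate_gaze <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  # screen capacity check: the largest saccade must fit from the centre
  amp_px <- max_amp_px(config)
  margin <- 60
  if (amp_px > min(config$screen_px) - 2 * margin)
    stopf(paste("screen too small: a %g-degree saccade spans %g px but only",
                "%g px are available"),
          config$amplitude_range_deg[2], amp_px,
          min(config$screen_px) - 2 * margin)
  with_seed(config$seed, {
    itis <- sample(config$iti_values_s, config$n_trials, replace = TRUE,
                   prob = config$iti_weights)
    onsets_s <- 2 + cumsum(c(0, head(config$trial_duration_s + itis, -1)))
    trials <- make_trials(onsets_s, config$trial_duration_s)
    total_s <- onsets_s[config$n_trials] + config$trial_duration_s +
      itis[config$n_trials] + 2
    n <- ceiling(total_s * config$sampling_rate_hz)
    step_ms <- 1000 / config$sampling_rate_hz
    time_ms <- (seq_len(n) - 1) * step_ms
    cx <- config$screen_px[1] / 2
    cy <- config$screen_px[2] / 2
    x <- numeric(n); y <- numeric(n)
    cur <- c(cx, cy)
    sac_list <- list()
    fill_from <- 1L
    for (t in seq_len(config$n_trials)) {
      t0 <- trials$onset_ms[t]
      t1 <- t0 + trials$duration_ms[t]
      n_sac <- stats::rpois(1, config$saccades_per_trial_mean)
      if (n_sac == 0) next
      cand <- sort(stats::runif(n_sac, t0 + 100, t1 - 80))
      keep <- rep(TRUE, n_sac)
      if (n_sac > 1) for (i in 2:n_sac) {
        last <- max(cand[seq_len(i - 1)][keep[seq_len(i - 1)]], -Inf)
        if (cand[i] - last < 150) keep[i] <- FALSE
      }
      cand <- cand[keep]
      for (on_ms in cand) {
        amp_deg <- stats::runif(1, config$amplitude_range_deg[1],
                                config$amplitude_range_deg[2])
        # main-sequence-like duration: ~21 ms intercept + 2.2 ms/deg
        dur_ms <- 21 + 2.2 * amp_deg + stats::runif(1, -2, 2)
        dxy <- NULL
        for (try in 1:50) {
          theta <- stats::runif(1, 0, 360)
          dxy <- sacc_displacement_px(amp_deg, theta, config)
          tgt <- cur + dxy
          if (tgt[1] > margin && tgt[1] < config$screen_px[1] - margin &&
              tgt[2] > margin && tgt[2] < config$screen_px[2] - margin)
            break
          dxy <- NULL
        }
        if (is.null(dxy)) {
          # aim back toward the centre with angular jitter, clamping the
          # landing point to the usable screen area
          theta <- wrap_deg(atan2(-(cy - cur[2]), cx - cur[1]) * 180 / pi +
                              stats::runif(1, -30, 30))
          dxy <- sacc_displacement_px(amp_deg, theta, config)
          tgt <- pmin(pmax(cur + dxy, margin + 1),
                      config$screen_px - margin - 1)
          dxy <- tgt - cur
          if (all(dxy == 0)) next
        }
        i0 <- floor(on_ms / step_ms) + 1L
        i1 <- min(floor((on_ms + dur_ms) / step_ms) + 1L, n)
        if (i1 <= i0 + 2L) next
        x[fill_from:i0] <- cur[1]
        y[fill_from:i0] <- cur[2]
        u <- (seq.int(i0, i1) - i0) / (i1 - i0)
        prof <- (1 - cos(pi * u)) / 2
        x[i0:i1] <- cur[1] + dxy[1] * prof
        y[i0:i1] <- cur[2] + dxy[2] * prof
        # ground-truth direction from the realized displacement
        sac_list[[length(sac_list) + 1L]] <- data.frame(
          onset_ms = time_ms[i0], offset_ms = time_ms[i1],
          direction_deg = compute_direction(cur, cur + dxy),
          amplitude_deg = amp_deg, trial_id = t)
        cur <- cur + dxy
        fill_from <- i1 + 1L
      }
    }
    x[fill_from:n] <- cur[1]
    y[fill_from:n] <- cur[2]
    x <- x + stats::rnorm(n, 0, config$gaze_noise_px)
    y <- y + stats::rnorm(n, 0, config$gaze_noise_px)
    pupil <- 3000 + stats::rnorm(n, 0, 10)
    # blinks: pupil dropout to 0 plus missing positions
    blink_list <- list()
    for (t in seq_len(config$n_trials)) {
      if (stats::runif(1) < config$blink_prob_per_trial) {
        b0 <- stats::runif(1, trials$onset_ms[t],
                           trials$onset_ms[t] + trials$duration_ms[t] - 300)
        bdur <- stats::runif(1, 100, 250)
        j <- which(time_ms >= b0 & time_ms <= b0 + bdur)
        pupil[j] <- 0
        x[j] <- NA_real_
        y[j] <- NA_real_
        blink_list[[length(blink_list) + 1L]] <-
          data.frame(start_ms = time_ms[j[1]],
                     end_ms = time_ms[j[length(j)]])
      }
    }
    true_sacc <- if (length(sac_list)) do.call(rbind, sac_list)
                 else data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                                 direction_deg = numeric(0),
                                 amplitude_deg = numeric(0),
                                 trial_id = integer(0))
    blinks <- if (length(blink_list)) do.call(rbind, blink_list)
              else data.frame(start_ms = numeric(0), end_ms = numeric(0))
    rec <- gaze_recording(time_ms, x, y, pupil, config$sampling_rate_hz,
                          config$screen_px, config$screen_cm,
                          config$viewing_distance_cm)
    list(recording = rec,
         truth = list(true_saccades = true_sacc, blink_intervals = blinks,
                      trials = trials,
                      true_orientation_deg = config$true_orientation_deg),
         trials = trials)
  })
}

# px extent of the largest saccade (diagonal-safe: use the finer axis)
max_amp_px <- function(config) {
  amp_cm <- tan(deg2rad(config$amplitude_range_deg[2])) *
    config$viewing_distance_cm
  amp_cm / min(config$screen_cm / config$screen_px)
}

# displacement in screen px for amplitude (deg) at math-frame angle theta
sacc_displacement_px <- function(amp_deg, theta_deg, config) {
  amp_cm <- tan(deg2rad(amp_deg)) * config$viewing_distance_cm
  th <- deg2rad(theta_deg)
  c(amp_cm * cos(th) / (config$screen_cm[1] / config$screen_px[1]),
    -amp_cm * sin(th) / (config$screen_cm[2] / config$screen_px[2]))
}

#' Generate ROI BOLD time series from a saccade list
#'
#' Places a neural impulse of height
#' `1 + a * cos(k * (alpha - phi0))` at each saccade onset, convolves with
#' the canonical HRF, and samples at the TR. Every voxel carries the same
#' directional signal plus independent Gaussian noise (optionally AR(1)),
#' a random linear drift, and the baseline. Six motion-like nuisance
#' traces (slow random walks) are produced alongside.
#'
#' @param saccades Data frame with `onset_ms` and `direction_deg` (e.g.
#'   the ground-truth list or a detected/retained subset).
#' @param config A [simulation_config()].
#' @param n_scans Number of volumes; defaults to covering the last
#'   saccade plus 16 s of hemodynamic tail.
#' @return List: `bold` (n_scans x n_voxels), `motion` (n_scans x 6),
#'   `n_scans`, `tr_s`, `neural_signal` (noise-free regressor at the TR).
#' @export
generate_roi_bold <- function(saccades, config, n_scans = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(saccades) == 0L) stopf("no saccades to generate BOLD from")
  onsets_s <- saccades$onset_ms / 1000
  if (is.null(n_scans))
    n_scans <- as.integer(ceiling((max(onsets_s) + 16) / config$tr_s))
  if (any(onsets_s > n_scans * config$tr_s))
    stopf("saccade onsets exceed the scan span")
  k <- config$symmetry_fold
  heights <- 1 + config$modulation_amplitude *
    cos(k * deg2rad(saccades$direction_deg - config$true_orientation_deg))
  hrf <- canonical_hrf(config$tr_s)
  signal <- convolve_train(onsets_s, rep(0, length(onsets_s)), heights,
                           n_scans, config$tr_s, hrf)
  with_seed(config$seed + 1L, {
    noise <- matrix(stats::rnorm(n_scans * config$n_voxels, 0,
                                 config$noise_sd),
                    n_scans, config$n_voxels)
    if (config$ar1_phi != 0) {
      noise <- apply(noise, 2, function(e)
        as.numeric(stats::filter(e, config$ar1_phi, method = "recursive")))
      noise <- noise * sqrt(1 - config$ar1_phi^2)
    }
    drift <- outer(seq(-0.5, 0.5, length.out = n_scans),
                   stats::rnorm(config$n_voxels, 0, config$drift_amplitude))
    motion <- apply(matrix(stats::rnorm(n_scans * 6, 0, 0.02), n_scans, 6),
                    2, cumsum)
    bold <- config$baseline + signal + noise + drift
    colnames(bold) <- paste0("v", seq_len(config$n_voxels))
    colnames(motion) <- paste0("mot", 1:6)
    list(bold = bold, motion = motion, n_scans = n_scans,
         tr_s = config$tr_s, neural_signal = signal)
  })
}

#' Generate recognition-memory responses from a signal-detection model
#'
#' Old-item memory strengths are Normal(`true_dprime`, 1) and new-item
#' strengths Normal(0, 1); the participant responds "old" iff the
#' strength exceeds `criterion`, and confidence ratings are assigned by
#' fixed strength cut-points around the criterion. The test list contains
#' all studied items plus half as many novel items.
#'
#' @param config A [simulation_config()].
#' @return Response table (data frame) with columns `trial_id`, `phase`,
#'   `status`, `rating`, `stim_id`; study rows first.
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_old <- config$n_trials
  n_new <- max(1L, round(config$n_trials / 2))
  with_seed(config$seed + 2L, {
    s_old <- stats::rnorm(n_old, config$true_dprime, 1)
    s_new <- stats::rnorm(n_new, 0, 1)
    cuts <- if (config$rating_scale == 6L) c(0.75, 0.25, 0, -0.25, -0.75)
            else c(0.5, 0, -0.5)
    rate <- function(s) {
      vapply(s, function(si) {
        sum(si <= config$criterion + cuts) + 1L
      }, integer(1))
    }
    study <- data.frame(trial_id = seq_len(n_old), phase = "study",
                        status = "old", rating = NA_integer_,
                        stim_id = sprintf("s%03d", seq_len(n_old)))
    test <- data.frame(
      trial_id = n_old + seq_len(n_old + n_new), phase = "test",
      status = c(rep("old", n_old), rep("new", n_new)),
      rating = c(rate(s_old), rate(s_new)),
      stim_id = c(sprintf("s%03d", seq_len(n_old)),
                  sprintf("n%03d", seq_len(n_new))))
    test <- test[sample.int(nrow(test)), ]
    test$trial_id <- n_old + seq_len(nrow(test))
    rownames(test) <- NULL
    rbind(study, test)
  })
}

#' Rating mapping for a scale
#'
#' @param rating_scale 6 or 4.
#' @return List with `old_ratings` and `new_ratings`.
#' @export
rating_mapping <- function(rating_scale) {
  if (rating_scale == 6L) list(old_ratings = 1:3, new_ratings = 4:6)
  else if (rating_scale == 4L) list(old_ratings = 1:2, new_ratings = 3:4)
  else stopf("rating_scale must be 4 or 6")
}

#' Match detected saccades against injected ground truth
#'
#' Greedy one-to-one matching by onset proximity within `tol_ms`.
#'
#' @param truth,detected Data frames with `onset_ms`.
#' @param tol_ms Matching tolerance (default 10 ms).
#' @return List: `precision`, `recall`, `n_matched`, `onset_errors_ms`.
#' @export
saccade_detection_score <- function(truth, detected, tol_ms = 10) {
  used <- logical(nrow(detected))
  errs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    d <- abs(detected$onset_ms - truth$onset_ms[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms) {
      used[j] <- TRUE
      errs <- c(errs, detected$onset_ms[j] - truth$onset_ms[i])
    }
  }
  n_matched <- sum(used)
  list(precision = if (nrow(detected)) n_matched / nrow(detected) else NA,
       recall = if (nrow(truth)) n_matched / nrow(truth) else NA,
       n_matched = n_matched, onset_errors_ms = errs)
}

#' Simulate a complete subject
#'
#' Runs the gaze, behavior, and BOLD generators for one subject and
#' (optionally) the saccade detection + exclusion pipeline, returning an
#' analysis-ready bundle. BOLD is always generated from the injected
#' (true) saccades; detection operates on the recording.
#'
#' @param config A [simulation_config()].
#' @param detect Run the velocity-threshold detector on the synthetic
#'   recording (`TRUE`) or analyze the ground-truth saccades directly
#'   (`FALSE`, much faster; used for large replication runs).
#' @param params [detection_params()] used when `detect = TRUE`.
#' @return List of class `subject_bundle`: `saccades` (retained,
#'   trial-linked), `trials` (with `memory` labels), `responses`, `bold`,
#'   `motion`, `n_scans`, `tr_s`, `truth`, `behavior_summary`, `config`.
#' @export
simulate_subject <- function(config, detect = TRUE,
                             params = detection_params("donders")) {
  gz <- generate_gaze(config)
  trials <- gz$trials
  responses <- generate_behavior(config)
  map <- rating_mapping(config$rating_scale)
  study <- responses[responses$phase == "study", c("trial_id", "stim_id")]
  study <- label_subsequent_memory(study, responses, map$old_ratings)
  trials$memory <- study$memory[match(trials$trial_id, study$trial_id)]
  counts <- bin_responses(responses, map$old_ratings, map$new_ratings)
  correction <- if (config$rating_scale == 6L) "loglinear" else "proportional"
  summary <- dprime(counts$n_hits, counts$n_fa, counts$n_signal,
                    counts$n_noise, correction)
  run_s <- max(trials$onset_s + trials$duration_s) + 16
  n_scans <- as.integer(ceiling(run_s / config$tr_s))
  roi <- generate_roi_bold(gz$truth$true_saccades, config, n_scans)
  if (detect) {
    det <- detect_saccades(gz$recording, params)
    blinks <- detect_blinks(gz$recording, params)
    sac <- filter_saccades(det, blinks, trials, gz$recording, params)
    sac <- retained_saccades(sac)
  } else {
    sac <- gz$truth$true_saccades
    sac$duration_ms <- sac$offset_ms - sac$onset_ms
    sac$excluded_reason <- "none"
  }
  structure(list(saccades = sac, trials = trials, responses = responses,
                 bold = roi$bold, motion = roi$motion,
                 n_scans = roi$n_scans, tr_s = config$tr_s,
                 recording = gz$recording, truth = gz$truth,
                 behavior_summary = summary, config = config),
            class = "subject_bundle")
}
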