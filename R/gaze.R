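#' Gaze recording container
#'
#' Sampled eye position and pupil trace together with the screen and
#' viewing geometry needed to convert pixels to degrees of visual angle.
#' Positions use screen-pixel coordinates with the origin at the top-left
#' corner and y increasing downward; missing samples (tracking loss,
#' blinks) are `NA`.
#'
#' @param time_ms Strictly increasing sample times, milliseconds.
#' @param x_px,y_px Gaze position channels, pixels.
#' @param pupil Pupil size, arbitrary units, `NA` allowed.
#' @param sampling_rate_hz Nominal sampling rate; must agree with the
#'   median time step within 1%.
#' @param screen_px,screen_cm Screen size as `c(width, height)` in pixels
#'   and centimetres.
#' @param viewing_distance_cm Eye-to-screen distance, centimetres.
#' @return A list of class `gaze_recording`.
#' @export
gaze_recording <- function(time_ms, x_px, y_px, pupil, sampling_rate_hz,
                           screen_px, screen_cm, viewing_distance_cm) {
  n <- length(time_ms)
  if (length(x_px) != n || length(y_px) != n || length(pupil) != n)
    stopf("gaze channels have unequal lengths")
  if (n < 2L || any(diff(time_ms) <= 0))
    stopf("time_ms must be strictly increasing with at least 2 samples")
  step <- stats::median(diff(time_ms))
  if (abs(step - 1000 / sampling_rate_hz) > 0.01 * (1000 / sampling_rate_hz))
    stopf("median time step (%g ms) inconsistent with sampling rate %g Hz",
          step, sampling_rate_hz)
  for (nm in c("screen_px", "screen_cm")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0))
      stopf("'%s' must be positive c(width, height)", nm)
  }
  check_number(viewing_distance_cm, "viewing_distance_cm",
               lower = .Machine$double.eps)
  structure(list(time_ms = as.numeric(time_ms), x_px = as.numeric(x_px),
                 y_px = as.numeric(y_px), pupil = as.numeric(pupil),
                 sampling_rate_hz = sampling_rate_hz,
                 screen_px = screen_px, screen_cm = screen_cm,
                 viewing_distance_cm = viewing_distance_cm),
            class = "gaze_recording")
}

#' Saccade detection and exclusion parameters
#'
#' Bundles the velocity-threshold detection constants and the
#' study-specific blink/adjacency exclusion rules. The `"donders"` profile
#' uses the mean +/- 5 SD pupil blink rule with a 100 ms pad and no
#' adjacent-saccade rule; `"vienna"` uses the 1 SD pupil rule with a
#' 300 ms blink pad and a 100 ms adjacent-saccade pad.
#'
#' @param study `"donders"` or `"vienna"`.
#' @param velocity_threshold_multiplier Saccades exceed this multiple of
#'   the SD of the pooled velocity distribution (default 6).
#' @param min_saccade_duration_ms Candidate runs must be strictly longer
#'   than this (default 12 ms).
#' @param min_fixation_before_ms Required subthreshold period preceding a
#'   saccade (default 25 ms).
#' @param blink_rule `"mean_5sd"` or `"mean_1sd"` pupil deviation rule.
#' @param blink_pad_ms Exclusion pad around blinks.
#' @param adjacent_saccade_pad_ms Exclusion pad between neighbouring
#'   saccades (0 disables the rule).
#' @param max_missing_fraction_per_trial Trials with a larger fraction of
#'   missing samples are discarded (default 0.25).
#' @param sd_estimator How the SD of the velocity distribution is
#'   estimated: `"median"` (default) uses the median-based robust
#'   estimator per axis with an elliptic suprathreshold criterion — the
#'   estimator the velocity-threshold algorithm of the eye-movement
#'   literature uses, insensitive to the saccadic samples themselves;
#'   `"moment"` uses the plain SD of the pooled speed distribution.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(study = c("donders", "vienna"),
                             velocity_threshold_multiplier = 6,
                             min_saccade_duration_ms = 12,
                             min_fixation_before_ms = 25,
                             blink_rule = NULL,
                             blink_pad_ms = NULL,
                             adjacent_saccade_pad_ms = NULL,
                             max_missing_fraction_per_trial = 0.25,
                             sd_estimator = c("median", "moment")) {
  study <- match.arg(study)
  sd_estimator <- match.arg(sd_estimator)
  if (is.null(blink_rule))
    blink_rule <- if (study == "donders") "mean_5sd" else "mean_1sd"
  if (is.null(blink_pad_ms))
    blink_pad_ms <- if (study == "donders") 100 else 300
  if (is.null(adjacent_saccade_pad_ms))
    adjacent_saccade_pad_ms <- if (study == "donders") 0 else 100
  check_number(velocity_threshold_multiplier, "velocity_threshold_multiplier",
               lower = .Machine$double.eps)
  check_number(blink_pad_ms, "blink_pad_ms", lower = 0)
  check_number(adjacent_saccade_pad_ms, "adjacent_saccade_pad_ms", lower = 0)
  structure(list(study = study,
                 velocity_threshold_multiplier = velocity_threshold_multiplier,
                 min_saccade_duration_ms = min_saccade_duration_ms,
                 min_fixation_before_ms = min_fixation_before_ms,
                 blink_rule = blink_rule,
                 blink_pad_ms = blink_pad_ms,
                 adjacent_saccade_pad_ms = adjacent_saccade_pad_ms,
                 max_missing_fraction_per_trial = max_missing_fraction_per_trial,
                 sd_estimator = sd_estimator),
            class = "detection_params")
}

#' Convert pixel gaze positions to degrees of visual angle
#'
#' Angular position relative to the screen centre via the arctangent of
#' the physical offset over the viewing distance. The horizontal axis is
#' positive rightward; the vertical axis is returned positive upward
#' (mathematical convention), i.e. the screen's y-down axis is flipped.
#'
#' @param recording A [gaze_recording()].
#' @return Data frame with columns `x_deg`, `y_deg`.
#' @export
px_to_deg <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  cmx <- recording$screen_cm[1] / recording$screen_px[1]
  cmy <- recording$screen_cm[2] / recording$screen_px[2]
  cx <- recording$screen_px[1] / 2
  cy <- recording$screen_px[2] / 2
  d <- recording$viewing_distance_cm
  data.frame(
    x_deg = atan((recording$x_px - cx) * cmx / d) * 180 / pi,
    y_deg = atan(-(recording$y_px - cy) * cmy / d) * 180 / pi
  )
}

#' Per-sample gaze velocity magnitude
#'
#' Central-difference velocity over a window of `smooth_window_samples`
#' samples per axis, combined as the Euclidean norm. Missing position
#' samples propagate to `NA` velocities. Units are px/s.
#'
#' @param recording A [gaze_recording()].
#' @param smooth_window_samples Width of the differencing window (>= 2);
#'   the default 5 gives the classic +/-2-sample central difference.
#' @return Numeric vector, `NA` at the edges.
#' @export
compute_velocity <- function(recording, smooth_window_samples = 5L) {
  velocity_xy(recording, smooth_window_samples)$speed
}

# per-axis central-difference velocities plus the speed norm
velocity_xy <- function(recording, smooth_window_samples = 5L) {
  stopifnot(inherits(recording, "gaze_recording"))
  w <- as.integer(smooth_window_samples)
  if (w < 2L) stopf("smooth_window_samples must be >= 2")
  n <- length(recording$time_ms)
  if (n < w) stopf("recording shorter than the velocity window")
  h <- w %/% 2L
  lead <- function(v, k) c(v[-seq_len(k)], rep(NA_real_, k))
  lag <- function(v, k) c(rep(NA_real_, k), v[seq_len(n - k)])
  dt_s <- (lead(recording$time_ms, h) - lag(recording$time_ms, h)) / 1000
  vx <- (lead(recording$x_px, h) - lag(recording$x_px, h)) / dt_s
  vy <- (lead(recording$y_px, h) - lag(recording$y_px, h)) / dt_s
  # any missing sample within the window poisons the velocity there
  bad <- is.na(recording$x_px) | is.na(recording$y_px)
  if (any(bad)) {
    in_win <- as.numeric(stats::filter(bad, rep(1, 2L * h + 1L),
                                       sides = 2)) > 0
    in_win[is.na(in_win)] <- TRUE
    vx[in_win] <- NA_real_
    vy[in_win] <- NA_real_
  }
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

# median-based robust SD (insensitive to the saccadic tail)
robust_sd <- function(v) {
  m <- stats::median(v, na.rm = TRUE)
  sqrt(stats::median(v^2, na.rm = TRUE) - m^2)
}

#' Detect blinks from the pupil channel
#'
#' Flags samples whose pupil size deviates from the mean by more than 5 SD
#' (`mean_5sd`) or 1 SD (`mean_1sd`); missing pupil samples count as blink
#' samples. Maximal flagged runs separated by fewer than 2 samples are
#' merged.
#'
#' @param recording A [gaze_recording()].
#' @param params A [detection_params()].
#' @return Data frame with columns `start_ms`, `end_ms` (possibly 0 rows).
#' @export
detect_blinks <- function(recording, params = detection_params("donders")) {
  stopifnot(inherits(recording, "gaze_recording"))
  p <- recording$pupil
  if (all(is.na(p))) stopf("pupil channel is entirely missing")
  mult <- switch(params$blink_rule, mean_5sd = 5, mean_1sd = 1,
                 stopf("unknown blink rule '%s'", params$blink_rule))
  mu <- mean(p, na.rm = TRUE)
  sdv <- stats::sd(p, na.rm = TRUE)
  bad <- is.na(p) | (sdv > 0 & abs(p - mu) > mult * sdv)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0L)
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  # merge runs separated by < 2 samples
  keep <- list(iv[1, ])
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      last <- keep[[length(keep)]]
      if (iv[i, 1] - last[2] - 1L < 2L)
        keep[[length(keep)]] <- c(last[1], iv[i, 2])
      else keep[[length(keep) + 1L]] <- iv[i, ]
    }
  }
  iv <- do.call(rbind, keep)
  data.frame(start_ms = recording$time_ms[iv[, 1]],
             end_ms = recording$time_ms[iv[, 2]])
}

#' Saccade direction angle
#'
#' Angle of the displacement from `start_xy` to `end_xy` in screen-pixel
#' coordinates (y down), returned in the mathematical y-up frame: 0 deg is
#' rightward on screen, 90 deg upward, counter-clockwise positive, range
#' [0, 360).
#'
#' @param start_xy,end_xy Numeric `c(x, y)` pixel positions.
#' @return Angle in degrees.
#' @export
compute_direction <- function(start_xy, end_xy) {
  dx <- end_xy[1] - start_xy[1]
  dy <- end_xy[2] - start_xy[2]
  if (dx == 0 && dy == 0) stopf("zero displacement: direction undefined")
  wrap_deg(atan2(-dy, dx) * 180 / pi)
}

#' Detect saccades with a velocity threshold
#'
#' Candidate saccades are maximal runs of samples whose velocity exceeds
#' `velocity_threshold_multiplier` times the SD of the velocity
#' distribution, computed over all non-missing samples of the recording.
#' With the default `"median"` estimator the SD is the median-based
#' robust estimate per axis and the threshold is elliptic; with
#' `"moment"` it is the plain SD of the pooled speed distribution.
#' A candidate is kept iff its duration strictly exceeds
#' `min_saccade_duration_ms` and it is preceded by at least
#' `min_fixation_before_ms` of contiguous subthreshold, non-missing
#' samples. Missing samples break suprathreshold runs.
#'
#' @param recording A [gaze_recording()].
#' @param params A [detection_params()].
#' @param smooth_window_samples Passed to [compute_velocity()].
#' @return Data frame of saccade events: onset/offset/duration (ms), start
#'   and end position (px), `direction_deg`, `amplitude_deg`,
#'   `peak_velocity` (px/s), `trial_id` (`NA` until assigned) and
#'   `excluded_reason` (`"none"`).
#' @export
detect_saccades <- function(recording, params = detection_params("donders"),
                            smooth_window_samples = 5L) {
  stopifnot(inherits(recording, "gaze_recording"))
  tm <- recording$time_ms
  if (tm[length(tm)] - tm[1] < 100) stopf("recording shorter than 100 ms")
  vel <- velocity_xy(recording, smooth_window_samples)
  v <- vel$speed
  if (params$sd_estimator == "moment") {
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0)
      stopf("velocity distribution has zero variance; threshold undefined")
    thr <- params$velocity_threshold_multiplier * sdv
    crit <- v / thr
  } else {
    sx <- robust_sd(vel$vx)
    sy <- robust_sd(vel$vy)
    if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
      stopf("velocity distribution has zero variance; threshold undefined")
    ex <- params$velocity_threshold_multiplier * sx
    ey <- params$velocity_threshold_multiplier * sy
    crit <- sqrt((vel$vx / ex)^2 + (vel$vy / ey)^2)
    thr <- c(x = ex, y = ey)
  }
  above <- !is.na(crit) & crit > 1
  below <- !is.na(crit) & crit <= 1
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  si <- starts[r$values]
  ei <- ends[r$values]
  out <- list()
  step_ms <- 1000 / recording$sampling_rate_hz
  n_fix <- ceiling(params$min_fixation_before_ms / step_ms)
  for (j in seq_along(si)) {
    i0 <- si[j]; i1 <- ei[j]
    dur <- tm[i1] - tm[i0]
    if (!(dur > params$min_saccade_duration_ms)) next
    if (i0 - n_fix < 1L) next
    pre <- (i0 - n_fix):(i0 - 1L)
    if (!all(below[pre])) next
    sxy <- c(recording$x_px[i0], recording$y_px[i0])
    exy <- c(recording$x_px[i1], recording$y_px[i1])
    if (anyNA(c(sxy, exy)) || all(sxy == exy)) next
    # amplitude in degrees from the angular positions of the endpoints
    cmx <- recording$screen_cm[1] / recording$screen_px[1]
    cmy <- recording$screen_cm[2] / recording$screen_px[2]
    d <- recording$viewing_distance_cm
    ang <- function(p) c(atan((p[1] - recording$screen_px[1] / 2) * cmx / d),
                         atan(-(p[2] - recording$screen_px[2] / 2) * cmy / d)) * 180 / pi
    amp <- sqrt(sum((ang(exy) - ang(sxy))^2))
    out[[length(out) + 1L]] <- data.frame(
      onset_ms = tm[i0], offset_ms = tm[i1], duration_ms = dur,
      start_x = sxy[1], start_y = sxy[2], end_x = exy[1], end_y = exy[2],
      direction_deg = compute_direction(sxy, exy), amplitude_deg = amp,
      peak_velocity = max(v[i0:i1]))
  }
  if (length(out) == 0L) {
    sac <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), start_x = numeric(0),
                      start_y = numeric(0), end_x = numeric(0),
                      end_y = numeric(0), direction_deg = numeric(0),
                      amplitude_deg = numeric(0), peak_velocity = numeric(0))
  } else sac <- do.call(rbind, out)
  sac$trial_id <- rep(NA_integer_, nrow(sac))
  sac$excluded_reason <- rep("none", nrow(sac))
  attr(sac, "velocity_threshold") <- thr
  sac
}

#' Apply blink, adjacency, and trial-quality exclusions
#'
#' Marks saccades overlapping any blink padded by `blink_pad_ms` as
#' excluded; when `adjacent_saccade_pad_ms > 0`, saccades within that pad
#' of a neighbouring saccade are excluded too. Saccades are then linked to
#' the enclosing trial (events outside trials are dropped), and all
#' saccades of trials whose fraction of missing gaze samples exceeds
#' `max_missing_fraction_per_trial` are excluded.
#'
#' @param saccades Output of [detect_saccades()].
#' @param blinks Output of [detect_blinks()].
#' @param trials Data frame with `trial_id`, `onset_ms`, `duration_ms`;
#'   windows must not overlap.
#' @param recording The [gaze_recording()] (for per-trial missing-data
#'   fractions).
#' @param params A [detection_params()].
#' @return The saccade table restricted to in-trial events, with
#'   `trial_id` set and `excluded_reason` in
#'   `none|blink|adjacent|trial_missing_data`.
#' @export
filter_saccades <- function(saccades, blinks, trials, recording,
                            params = detection_params("donders")) {
  if (nrow(trials) > 1L) {
    o <- order(trials$onset_ms)
    tr <- trials[o, ]
    if (any(tr$onset_ms[-1] < (tr$onset_ms + tr$duration_ms)[-nrow(tr)]))
      stopf("trial windows overlap")
  }
  sac <- saccades
  n <- nrow(sac)
  if (n == 0L) return(sac)
  reason <- sac$excluded_reason
  # blink exclusion on the full detected set
  if (nrow(blinks) > 0L) {
    for (b in seq_len(nrow(blinks))) {
      s <- blinks$start_ms[b] - params$blink_pad_ms
      e <- blinks$end_ms[b] + params$blink_pad_ms
      hit <- sac$onset_ms <= e & sac$offset_ms >= s
      reason[hit & reason == "none"] <- "blink"
    }
  }
  # adjacent-saccade exclusion (both members)
  if (params$adjacent_saccade_pad_ms > 0 && n > 1L) {
    o <- order(sac$onset_ms)
    gap <- sac$onset_ms[o][-1] - sac$offset_ms[o][-n]
    close_pair <- gap < params$adjacent_saccade_pad_ms
    adj <- logical(n)
    adj[o[-n][close_pair]] <- TRUE
    adj[o[-1][close_pair]] <- TRUE
    reason[adj & reason == "none"] <- "adjacent"
  }
  # trial linkage + per-trial missing-data rule
  trial_id <- rep(NA_integer_, n)
  for (t in seq_len(nrow(trials))) {
    t0 <- trials$onset_ms[t]
    t1 <- t0 + trials$duration_ms[t]
    inside <- sac$onset_ms >= t0 & sac$onset_ms < t1
    trial_id[inside] <- trials$trial_id[t]
    idx <- recording$time_ms >= t0 & recording$time_ms < t1
    frac <- mean(is.na(recording$x_px[idx]) | is.na(recording$y_px[idx]))
    if (frac > params$max_missing_fraction_per_trial)
      reason[inside & reason == "none"] <- "trial_missing_data"
  }
  sac$excluded_reason <- reason
  sac$trial_id <- trial_id
  sac[!is.na(trial_id), , drop = FALSE]
}

#' Retained (analysis-ready) saccades
#'
#' @param saccades Output of [filter_saccades()].
#' @return Rows with `excluded_reason == "none"`.
#' @export
retained_saccades <- function(saccades) {
  saccades[saccades$excluded_reason == "none", , drop = FALSE]
}
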