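#' Study analysis profile
#'
#' Named parameter sets binding each study's constants: detection and
#' exclusion rules, rating-scale mapping, d-prime correction, repetition
#' time, trial duration, and ROI quality thresholds (voxel quality score
#' 0.8, minimum 14 voxels, minimum 30 saccades per condition).
#'
#' @param name `"donders"` (6-point scale, log-linear correction,
#'   TR 0.657 s, 4 s scenes) or `"vienna"` (4-point scale, proportional
#'   correction, TR 2.029 s, 3 s scenes).
#' @return List of class `study_profile`.
#' @export
study_profile <- function(name = c("donders", "vienna")) {
  name <- match.arg(name)
  if (name == "donders") {
    p <- list(name = name, detection = detection_params("donders"),
              rating_scale = 6L, dprime_correction = "loglinear",
              tr_s = 0.657, trial_duration_s = 4)
  } else {
    p <- list(name = name, detection = detection_params("vienna"),
              rating_scale = 4L, dprime_correction = "proportional",
              tr_s = 2.029, trial_duration_s = 3)
  }
  p$rating_map <- rating_mapping(p$rating_scale)
  p$min_roi_voxels <- 14L
  p$voxel_quality_threshold <- 0.8
  p$min_saccades <- 30L
  structure(p, class = "study_profile")
}

#' Filter ROI voxels by a quality score
#'
#' Default score is each voxel's temporal mean divided by the grand mean
#' of all voxel means (relative mean intensity); `method = "tsnr"` uses
#' temporal mean / temporal SD instead. Voxels scoring below `threshold`
#' are dropped; fewer than `min_voxels` survivors is a subject-exclusion
#' error.
#'
#' @param bold n_scans x n_voxels matrix.
#' @param threshold Quality threshold (default 0.8).
#' @param min_voxels Minimum surviving voxel count (default 14).
#' @param method `"relative_mean"` or `"tsnr"`.
#' @return The filtered matrix, with attribute `quality_scores`.
#' @export
voxel_quality_filter <- function(bold, threshold = 0.8, min_voxels = 14L,
                                 method = c("relative_mean", "tsnr")) {
  method <- match.arg(method)
  bold <- as.matrix(bold)
  if (ncol(bold) < 1L) stopf("empty ROI")
  mu <- colMeans(bold)
  score <- switch(method,
                  relative_mean = mu / mean(mu),
                  tsnr = mu / apply(bold, 2, stats::sd))
  keep <- score >= threshold
  if (sum(keep) < min_voxels)
    stopf("subject excluded: only %d voxels pass the quality threshold (minimum %d)",
          sum(keep), min_voxels)
  out <- bold[, keep, drop = FALSE]
  attr(out, "quality_scores") <- score
  out
}

#' Write a simulated subject as a plain-text fixture set
#'
#' Emits `gaze.csv` (time_ms, x_px, y_px, pupil), `events.tsv` (study
#' trials, BIDS-events style), `responses.tsv`, `roi_ec.tsv`
#' (volumes x voxels), `motion.tsv`, and `truth.json` into `dir`.
#'
#' @param subject A `subject_bundle` from [simulate_subject()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- subject$recording
  gaze <- data.frame(time_ms = rec$time_ms, x_px = rec$x_px,
                     y_px = rec$y_px, pupil = rec$pupil)
  utils::write.csv(gaze, file.path(dir, "gaze.csv"), row.names = FALSE)
  ev <- data.frame(onset = subject$trials$onset_s,
                   duration = subject$trials$duration_s,
                   trial_type = "scene",
                   stim_id = sprintf("s%03d", subject$trials$trial_id),
                   trial_id = subject$trials$trial_id)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(subject$responses, file.path(dir, "responses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format(subject$bold, digits = 17, trim = TRUE),
                     file.path(dir, "roi_ec.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(format(subject$motion, digits = 17, trim = TRUE),
                     file.path(dir, "motion.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- subject$truth
  truth$geometry <- list(sampling_rate_hz = rec$sampling_rate_hz,
                         screen_px = rec$screen_px,
                         screen_cm = rec$screen_cm,
                         viewing_distance_cm = rec$viewing_distance_cm,
                         tr_s = subject$tr_s, n_scans = subject$n_scans)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a subject fixture directory
#'
#' Reads the files written by [write_subject()] and validates the
#' recording, trial table, and matrix shapes.
#'
#' @param dir Directory containing `gaze.csv`, `events.tsv`,
#'   `responses.tsv`, `roi_ec.tsv`, `motion.tsv`, `truth.json`.
#' @param profile A [study_profile()].
#' @return A `subject_bundle` (without detection applied; `saccades` is
#'   `NULL` until [detect_and_filter()] is run).
#' @export
read_subject <- function(dir, profile = study_profile("donders")) {
  need <- c("gaze.csv", "events.tsv", "responses.tsv", "roi_ec.tsv",
            "motion.tsv", "truth.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stopf("missing subject files: %s", paste(missing, collapse = ", "))
  gaze <- utils::read.csv(file.path(dir, "gaze.csv"))
  for (col in c("time_ms", "x_px", "y_px", "pupil"))
    if (!col %in% names(gaze)) stopf("gaze.csv is missing column '%s'", col)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  geom <- truth$geometry
  rec <- gaze_recording(gaze$time_ms, gaze$x_px, gaze$y_px, gaze$pupil,
                        geom$sampling_rate_hz, unlist(geom$screen_px),
                        unlist(geom$screen_cm), geom$viewing_distance_cm)
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  for (col in c("onset", "duration", "trial_id"))
    if (!col %in% names(ev)) stopf("events.tsv is missing column '%s'", col)
  trials <- data.frame(trial_id = ev$trial_id, onset_ms = ev$onset * 1000,
                       duration_ms = ev$duration * 1000,
                       onset_s = ev$onset, duration_s = ev$duration)
  responses <- utils::read.delim(file.path(dir, "responses.tsv"))
  bold <- as.matrix(utils::read.delim(file.path(dir, "roi_ec.tsv")))
  motion <- as.matrix(utils::read.delim(file.path(dir, "motion.tsv")))
  if (nrow(motion) != nrow(bold))
    stopf("motion rows (%d) do not match volume count (%d)",
          nrow(motion), nrow(bold))
  if (nrow(bold) * geom$tr_s < max(trials$onset_s + trials$duration_s))
    stopf("scan span does not cover all trial onsets (TR mismatch?)")
  map <- rating_mapping(profile$rating_scale)
  study <- responses[responses$phase == "study", c("trial_id", "stim_id")]
  study <- label_subsequent_memory(study, responses, map$old_ratings)
  trials$memory <- study$memory[match(trials$trial_id, study$trial_id)]
  structure(list(saccades = NULL, trials = trials, responses = responses,
                 bold = bold, motion = motion, n_scans = nrow(bold),
                 tr_s = geom$tr_s, recording = rec, truth = truth,
                 behavior_summary = NULL, config = NULL,
                 profile = profile$name),
            class = "subject_bundle")
}

#' Extract an ROI time-series matrix from a 4-D NIfTI image and mask
#'
#' Reads a 4-D BOLD image and a binary 3-D mask and returns the
#' volumes x voxels matrix of in-mask voxel time courses, columns in
#' linear (array) mask order.
#'
#' @param bold_path Path to a 4-D NIfTI image.
#' @param mask_path Path to a binary NIfTI mask with matching 3-D
#'   dimensions.
#' @return Numeric matrix, `n_volumes` x `n_in_mask_voxels`.
#' @export
read_roi_nifti <- function(bold_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("the RNifti package is required to read NIfTI input")
  img <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  d <- dim(img)
  if (length(d) != 4L) stopf("expected a 4-D image, got %d dims", length(d))
  if (length(dim(mask)) != 3L || !all(dim(mask) == d[1:3]))
    stopf("mask dimensions do not match the image")
  keep <- which(as.array(mask) != 0)
  if (length(keep) == 0L) stopf("empty mask")
  flat <- matrix(as.array(img), prod(d[1:3]), d[4])
  out <- t(flat[keep, , drop = FALSE])
  colnames(out) <- paste0("v", seq_along(keep))
  out
}

#' Detect, filter, and attach saccades to a subject bundle
#'
#' @param subject A `subject_bundle` with a `recording`.
#' @param profile A [study_profile()] supplying the detection rules.
#' @return The bundle with `saccades` set to the retained events.
#' @export
detect_and_filter <- function(subject, profile = study_profile("donders")) {
  det <- detect_saccades(subject$recording, profile$detection)
  blinks <- detect_blinks(subject$recording, profile$detection)
  sac <- filter_saccades(det, blinks, subject$trials, subject$recording,
                         profile$detection)
  subject$saccades <- retained_saccades(sac)
  subject$all_saccades <- sac
  subject
}

#' Run the complete per-subject analysis
#'
#' Saccade detection (if not already attached), behavioral scoring, the
#' split-half grid analysis across symmetry folds, partition orders and
#' conditions, the combined trial-wise series, and the duration-bias
#' diagnostic. Optionally writes tidy TSV tables with a JSON sidecar.
#'
#' @param subject A `subject_bundle`.
#' @param profile A [study_profile()].
#' @param folds,orders,conditions Passed to [grid_analysis()].
#' @param out_dir If non-`NULL`, write `saccades.tsv`, `behavior.tsv`,
#'   `grid.tsv`, `trial_series.tsv`, and `provenance.json` there.
#' @return List: `saccades`, `behavior`, `grid`, `trial_series`,
#'   `duration_bias`.
#' @export
run_subject <- function(subject, profile = study_profile("donders"),
                        folds = c(4L, 5L, 6L, 7L, 8L),
                        orders = c("forward", "reversed"),
                        conditions = "all", out_dir = NULL) {
  if (is.null(subject$saccades))
    subject <- detect_and_filter(subject, profile)
  map <- rating_mapping(profile$rating_scale)
  counts <- bin_responses(subject$responses, map$old_ratings,
                          map$new_ratings)
  behav <- dprime(counts$n_hits, counts$n_fa, counts$n_signal,
                  counts$n_noise, profile$dprime_correction)
  grid <- grid_analysis(subject, folds = folds, orders = orders,
                        conditions = conditions,
                        min_saccades = profile$min_saccades)
  series <- grid_trial_series(subject, k = 6L,
                              min_saccades = profile$min_saccades)
  bias <- direction_bias_test(subject$saccades)
  res <- list(saccades = subject$saccades,
              behavior = as.data.frame(behav[c("n_hits", "n_misses", "n_fa",
                                               "n_cr", "hit_rate", "fa_rate",
                                               "d_prime", "correction")]),
              grid = grid, trial_series = series,
              duration_bias = data.frame(statistic = bias$statistic,
                                         df = bias$df, p = bias$p))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("saccades", "behavior", "grid", "trial_series",
                 "duration_bias"))
      utils::write.table(format(res[[nm]], digits = 17, trim = TRUE),
                         file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(profile = profile$name,
           seed = if (!is.null(subject$config)) subject$config$seed else NA,
           package_version = as.character(utils::packageVersion("gridgaze"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  res
}

#' Group-level analysis over subject results
#'
#' For each (roi, k, order, condition) cell: MAD +/- 3 outlier exclusion,
#' then a one-tailed (greater) signed-rank test of the grid magnitudes
#' against zero with Cohen's d and the Bonferroni threshold for the
#' number of folds tested. Adds Pearson correlations of the 6-fold
#' forward magnitudes with d-prime, hit rate, and mean saccade count.
#'
#' @param subject_results List of [run_subject()] outputs.
#' @param alpha Nominal level (default 0.05).
#' @return List: `tests` (data frame per cell), `correlations`,
#'   `alpha_bonferroni`.
#' @export
run_group <- function(subject_results, alpha = 0.05) {
  if (length(subject_results) < 2L) stopf("need at least 2 subjects")
  grids <- lapply(subject_results, `[[`, "grid")
  cells <- unique(do.call(rbind, lapply(grids, function(g)
    g[, c("roi", "k", "order", "condition")])))
  n_folds <- length(unique(cells$k))
  thr <- bonferroni_alpha(alpha, n_folds)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    vals <- vapply(grids, function(g) {
      j <- g$roi == cells$roi[i] & g$k == cells$k[i] &
        g$order == cells$order[i] & g$condition == cells$condition[i]
      if (any(j)) g$magnitude[j][1] else NA_real_
    }, 0)
    vals <- vals[!is.na(vals)]
    filt <- mad_outlier_filter(vals)
    kept <- filt$retained
    row <- cbind(cells[i, ], n = length(kept),
                 n_outliers = length(filt$excluded_idx))
    if (length(kept) < 3L || stats::sd(kept) == 0 || all(kept == 0)) {
      warning(sprintf("cell %s/k=%d/%s/%s untestable; skipped",
                      cells$roi[i], cells$k[i], cells$order[i],
                      cells$condition[i]))
      row$V <- NA; row$p <- NA; row$d <- NA
    } else {
      wt <- wilcoxon_signed_rank(kept, 0, "greater")
      row$V <- wt$statistic; row$p <- wt$p; row$d <- wt$effect_size_d
    }
    row$mean <- mean(kept)
    row$sem <- stats::sd(kept) / sqrt(length(kept))
    row$significant_bonferroni <- !is.na(row$p) & row$p < thr
    rows[[i]] <- row
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  # brain-behavior correlations on the 6-fold forward magnitudes
  mag6 <- vapply(grids, function(g) {
    j <- g$k == 6 & g$order == "forward" & g$condition == "all"
    if (any(j)) g$magnitude[j][1] else NA_real_
  }, 0)
  dpr <- vapply(subject_results, function(s) s$behavior$d_prime, 0)
  hr <- vapply(subject_results, function(s) s$behavior$hit_rate, 0)
  nsac <- vapply(subject_results, function(s)
    nrow(s$saccades) / length(unique(s$saccades$trial_id)), 0)
  correlations <- list()
  for (nm in c("d_prime", "hit_rate", "saccade_count")) {
    y <- switch(nm, d_prime = dpr, hit_rate = hr, saccade_count = nsac)
    correlations[[nm]] <- tryCatch(pearson_with_ci(mag6, y),
                                   error = function(e) NULL)
  }
  list(tests = tests, correlations = correlations, alpha_bonferroni = thr)
}
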