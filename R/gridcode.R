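#' Split saccades into estimation and test halves
#'
#' Contiguous-in-time split at the trial midpoint: the first
#' `ceiling(n/2)` trials (by onset) form the estimation set and the rest
#' the test set; `order = "reversed"` swaps the roles. Every retained
#' saccade falls in exactly one half.
#'
#' @param saccades Retained, trial-linked saccade table.
#' @param trials Trial table with `trial_id` and `onset_ms`.
#' @param order `"forward"` or `"reversed"`.
#' @param min_saccades Minimum saccades per half (default 30); fewer is
#'   an error, mirroring the participant-exclusion rule.
#' @return List: `estimation`, `test` (saccade tables), `estimation_trials`,
#'   `test_trials` (trial-id vectors), `order`.
#' @export
split_halves <- function(saccades, trials, order = c("forward", "reversed"),
                         min_saccades = 30L) {
  order <- match.arg(order)
  if (nrow(trials) < 2L) stopf("need at least 2 trials to split")
  ord <- trials$trial_id[order(trials$onset_ms)]
  n_first <- ceiling(length(ord) / 2)
  first <- ord[seq_len(n_first)]
  second <- ord[-seq_len(n_first)]
  est_ids <- if (order == "forward") first else second
  test_ids <- if (order == "forward") second else first
  est <- saccades[saccades$trial_id %in% est_ids, , drop = FALSE]
  tst <- saccades[saccades$trial_id %in% test_ids, , drop = FALSE]
  if (nrow(est) < min_saccades || nrow(tst) < min_saccades)
    stopf("a data half has fewer than %d saccades (%d / %d)",
          min_saccades, nrow(est), nrow(tst))
  list(estimation = est, test = tst, estimation_trials = est_ids,
       test_trials = test_ids, order = order)
}

# shared design scaffolding for the two grid GLMs
grid_design <- function(task_cols, motion, n_scans, tr_s) {
  hp <- dct_highpass_basis(n_scans, tr_s)
  nuis <- if (!is.null(motion)) motion_nuisance(motion) else NULL
  assemble_design(task_cols, nuisance = nuis, highpass = hp)
}

#' Estimate quadrature betas (orientation-estimation GLM)
#'
#' First-stage GLM: sticks for the estimation-half saccades plus two
#' parametric modulators, the mean-centered sin(k*alpha) and
#' cos(k*alpha); the other half's saccades enter as an unmodulated stick
#' regressor; motion nuisance (6 parameters, derivatives, squared
#' derivatives), the 128 s DCT high-pass basis, and an intercept complete
#' the design. Returns the per-voxel coefficients of the two modulators.
#'
#' @param bold n_scans x n_voxels BOLD matrix.
#' @param est_saccades,other_saccades Saccade tables with `onset_ms`,
#'   `direction_deg`.
#' @param motion n_scans x 6 motion parameters (or `NULL`).
#' @param k Symmetry fold.
#' @param tr_s Repetition time.
#' @param extra_saccades Optional unmodulated nuisance events (e.g.
#'   saccades during non-scene stimuli), same columns.
#' @return List: `beta_sin`, `beta_cos` (per voxel), `k`, `n_est`.
#' @export
estimate_quadrature <- function(bold, est_saccades, other_saccades, motion,
                                k, tr_s, extra_saccades = NULL) {
  bold <- as.matrix(bold)
  n_scans <- nrow(bold)
  hrf <- canonical_hrf(tr_s)
  a <- deg2rad(est_saccades$direction_deg)
  est_sin <- build_regressor(
    event_list(est_saccades$onset_ms / 1000, 0, sin(k * a), "est"),
    n_scans, tr_s, hrf)
  est_cos <- build_regressor(
    event_list(est_saccades$onset_ms / 1000, 0, cos(k * a), "est"),
    n_scans, tr_s, hrf)
  task <- cbind(est_sin[, "est"], est_sin[, "est_pmod"],
                est_cos[, "est_pmod"])
  colnames(task) <- c("est", "est_sin", "est_cos")
  if (nrow(other_saccades) > 0L) {
    oth <- build_regressor(
      event_list(other_saccades$onset_ms / 1000, 0, name = "test_unmod"),
      n_scans, tr_s, hrf)
    task <- cbind(task, oth)
  }
  if (!is.null(extra_saccades) && nrow(extra_saccades) > 0L) {
    ex <- build_regressor(
      event_list(extra_saccades$onset_ms / 1000, 0, name = "nuis_sacc"),
      n_scans, tr_s, hrf)
    task <- cbind(task, ex)
  }
  X <- grid_design(task, motion, n_scans, tr_s)
  fit <- fit_glm(bold, X)
  list(beta_sin = fit$coefficients["est_sin", ],
       beta_cos = fit$coefficients["est_cos", ],
       k = k, n_est = nrow(est_saccades))
}

#' Grid orientation from quadrature betas
#'
#' phi = atan2(mean(beta_sin), mean(beta_cos)) / k, wrapped into
#' [0, 360/k). The two-argument arctangent resolves the quadrant that the
#' plain arctan of the beta ratio leaves ambiguous.
#'
#' @param betas Output of [estimate_quadrature()].
#' @param k Symmetry fold (defaults to the one stored in `betas`).
#' @return List: `phi_deg`, `k`.
#' @export
orientation_from_betas <- function(betas, k = betas$k) {
  ms <- mean(betas$beta_sin)
  mc <- mean(betas$beta_cos)
  if (ms == 0 && mc == 0) stopf("mean betas are both zero; orientation undefined")
  phi <- wrap_deg(atan2(ms, mc) * 180 / pi) / k
  list(phi_deg = wrap_deg(phi, 360 / k), k = k)
}

#' Test grid alignment on held-out saccades (alignment GLM)
#'
#' Second-stage GLM: the estimation half's saccades are unmodulated; the
#' test half's saccades get a parametric modulator, the mean-centered
#' cos(k*(alpha - phi)) with phi estimated on the opposite half. With a
#' condition restriction (e.g. hit trials), only the condition's test
#' saccades are modulated and the rest stay unmodulated. The grid
#' magnitude is the ROI mean of the modulator's voxel betas.
#'
#' @param bold n_scans x n_voxels BOLD matrix.
#' @param test_saccades,est_saccades Saccade tables.
#' @param phi Orientation (degrees) from the opposite data half, or the
#'   list returned by [orientation_from_betas()].
#' @param motion Motion parameters or `NULL`.
#' @param k Symmetry fold.
#' @param tr_s Repetition time.
#' @param condition_trials Optional trial ids: only test saccades in these
#'   trials are modulated.
#' @param min_saccades Minimum modulated saccades (default 30).
#' @param extra_saccades Optional unmodulated nuisance events.
#' @return List: `value` (mean test beta), `voxel_betas`, `phi_deg`, `k`,
#'   `n_test_saccades`.
#' @export
test_alignment <- function(bold, test_saccades, est_saccades, phi, motion,
                           k, tr_s, condition_trials = NULL,
                           min_saccades = 30L, extra_saccades = NULL) {
  if (is.list(phi)) phi <- phi$phi_deg
  bold <- as.matrix(bold)
  n_scans <- nrow(bold)
  hrf <- canonical_hrf(tr_s)
  mod_set <- test_saccades
  if (!is.null(condition_trials))
    mod_set <- test_saccades[test_saccades$trial_id %in% condition_trials, ,
                             drop = FALSE]
  if (nrow(mod_set) < min_saccades)
    stopf("only %d modulated test saccades; minimum is %d",
          nrow(mod_set), min_saccades)
  align <- cos(k * deg2rad(mod_set$direction_deg - phi))
  task <- build_regressor(
    event_list(est_saccades$onset_ms / 1000, 0, name = "est_unmod"),
    n_scans, tr_s, hrf)
  test_unmod <- build_regressor(
    event_list(test_saccades$onset_ms / 1000, 0, name = "test"),
    n_scans, tr_s, hrf)
  test_pmod <- build_regressor(
    event_list(mod_set$onset_ms / 1000, 0, align, "testmod"),
    n_scans, tr_s, hrf)[, "testmod_pmod", drop = FALSE]
  task <- cbind(task, test_unmod, test_pmod)
  if (!is.null(extra_saccades) && nrow(extra_saccades) > 0L) {
    ex <- build_regressor(
      event_list(extra_saccades$onset_ms / 1000, 0, name = "nuis_sacc"),
      n_scans, tr_s, hrf)
    task <- cbind(task, ex)
  }
  X <- grid_design(task, motion, n_scans, tr_s)
  fit <- fit_glm(bold, X)
  vb <- fit$coefficients["testmod_pmod", ]
  list(value = mean(vb), voxel_betas = vb, phi_deg = phi, k = k,
       n_test_saccades = nrow(mod_set))
}

#' Full split-half grid analysis for one subject
#'
#' For each symmetry fold, partition order, and condition: estimate the
#' grid orientation on the estimation half (always from all trials of
#' that half, regardless of condition), then quantify alignment of the
#' held-out saccades. Conditions `"hits"`/`"misses"` restrict the
#' modulated test saccades to trials with the respective memory label.
#'
#' @param subject A `subject_bundle` from [simulate_subject()] or
#'   [read_subject()] + detection.
#' @param folds Symmetry folds to run (default `c(4, 5, 6, 7, 8)`).
#' @param orders Partition orders (default both).
#' @param conditions Subset of `c("all", "hits", "misses")`.
#' @param roi ROI label recorded in the output.
#' @param min_saccades Per-half and per-condition minimum.
#' @return Data frame: one row per (roi, k, order, condition) with
#'   `phi_deg`, `magnitude`, `n_est`, `n_test`.
#' @export
grid_analysis <- function(subject, folds = c(4L, 5L, 6L, 7L, 8L),
                          orders = c("forward", "reversed"),
                          conditions = "all", roi = "ec",
                          min_saccades = 30L) {
  out <- list()
  for (ord in orders) {
    sp <- split_halves(subject$saccades, subject$trials, ord, min_saccades)
    for (k in folds) {
      qb <- estimate_quadrature(subject$bold, sp$estimation, sp$test,
                                subject$motion, k, subject$tr_s)
      phi <- orientation_from_betas(qb)
      for (cond in conditions) {
        ct <- switch(cond,
                     all = NULL,
                     hits = subject$trials$trial_id[
                       !is.na(subject$trials$memory) &
                         subject$trials$memory == "hit"],
                     misses = subject$trials$trial_id[
                       !is.na(subject$trials$memory) &
                         subject$trials$memory == "miss"],
                     stopf("unknown condition '%s'", cond))
        mag <- test_alignment(subject$bold, sp$test, sp$estimation, phi,
                              subject$motion, k, subject$tr_s,
                              condition_trials = ct,
                              min_saccades = min_saccades)
        out[[length(out) + 1L]] <- data.frame(
          roi = roi, k = k, order = ord, condition = cond,
          phi_deg = phi$phi_deg, magnitude = mag$value,
          n_est = nrow(sp$estimation), n_test = mag$n_test_saccades)
      }
    }
  }
  do.call(rbind, out)
}

#' Trial-wise grid-alignment series
#'
#' Per-saccade alignment value cos(k*(alpha - phi)) averaged within each
#' trial. `phi` must come from the opposite data half; to cover all
#' trials, run both partition orders and combine (see
#' [grid_trial_series()]).
#'
#' @param test_saccades Saccade table (the held-out half).
#' @param phi Orientation in degrees (or [orientation_from_betas()]
#'   output).
#' @param k Symmetry fold.
#' @param trial_ids Trials to report; defaults to those present in
#'   `test_saccades`. Trials without retained saccades get `NA`.
#' @return Data frame: `trial_id`, `value` (in [-1, 1]), `n_saccades`.
#' @export
trialwise_magnitudes <- function(test_saccades, phi, k,
                                 trial_ids = NULL) {
  if (is.list(phi)) phi <- phi$phi_deg
  if (is.null(trial_ids)) trial_ids <- sort(unique(test_saccades$trial_id))
  val <- cos(k * deg2rad(test_saccades$direction_deg - phi))
  out <- data.frame(trial_id = trial_ids, value = NA_real_,
                    n_saccades = 0L)
  for (i in seq_along(trial_ids)) {
    j <- test_saccades$trial_id == trial_ids[i]
    out$n_saccades[i] <- sum(j)
    if (any(j)) out$value[i] <- mean(val[j])
  }
  out
}

#' Trial series over both partition orders
#'
#' Runs the orientation-estimation GLM in both partition orders and
#' concatenates the held-out trial-wise alignment values, so every trial
#' receives a value estimated from the opposite data half.
#'
#' @param subject A `subject_bundle`.
#' @param k Symmetry fold (default 6).
#' @param min_saccades Per-half minimum.
#' @return Data frame as in [trialwise_magnitudes()], all trials.
#' @export
grid_trial_series <- function(subject, k = 6L, min_saccades = 30L) {
  parts <- lapply(c("forward", "reversed"), function(ord) {
    sp <- split_halves(subject$saccades, subject$trials, ord, min_saccades)
    qb <- estimate_quadrature(subject$bold, sp$estimation, sp$test,
                              subject$motion, k, subject$tr_s)
    phi <- orientation_from_betas(qb)
    trialwise_magnitudes(sp$test, phi, k, trial_ids = sp$test_trials)
  })
  res <- do.call(rbind, parts)
  res[order(res$trial_id), , drop = FALSE]
}

#' Trial-modulation GLM (subsequent whole-brain-style analysis)
#'
#' A single boxcar task regressor covering every included trial,
#' parametrically modulated by the mean-centered trial-wise grid values,
#' plus motion nuisance, high-pass basis, and intercept. Returns the
#' per-voxel modulator beta (the subject-level contrast of trial-wise
#' grid-code fluctuations against implicit baseline).
#'
#' @param bold n_scans x n_voxels matrix.
#' @param trials Trial table with `onset_s`, `duration_s`.
#' @param trial_series Output of [grid_trial_series()].
#' @param motion Motion parameters or `NULL`.
#' @param tr_s Repetition time.
#' @param drop_missing Drop trials with `NA` series values (default
#'   `FALSE`, which errors on missing values).
#' @return List: `beta` (per voxel), `design`, `n_trials`.
#' @export
build_trial_parametric_design <- function(bold, trials, trial_series,
                                          motion, tr_s,
                                          drop_missing = FALSE) {
  bold <- as.matrix(bold)
  n_scans <- nrow(bold)
  v <- trial_series$value[match(trials$trial_id, trial_series$trial_id)]
  if (anyNA(v)) {
    if (!drop_missing)
      stopf("missing trial-wise values for trial(s): %s",
            paste(trials$trial_id[is.na(v)], collapse = ", "))
    trials <- trials[!is.na(v), , drop = FALSE]
    v <- v[!is.na(v)]
  }
  if (stats::sd(v) == 0)
    stopf("constant trial series: parametric column is zero after centering")
  hrf <- canonical_hrf(tr_s)
  task <- build_regressor(
    event_list(trials$onset_s, trials$duration_s, v, "scene"),
    n_scans, tr_s, hrf)
  X <- grid_design(task, motion, n_scans, tr_s)
  fit <- fit_glm(bold, X)
  list(beta = fit$coefficients["scene_pmod", ], design = X,
       n_trials = nrow(trials))
}
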