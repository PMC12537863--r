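#' Orientation-recovery and symmetry-specificity study
#'
#' Simulates a cohort of subjects with a common ground-truth setup
#' (6-fold modulation, amplitude `a`, Gaussian BOLD noise), runs the full
#' pipeline (gaze synthesis, saccade detection and exclusion, split-half
#' quadrature estimation, held-out alignment test) per subject, and
#' summarizes: the median circular orientation error in 360/k space and
#' the one-tailed group signed-rank p-value of the alignment magnitudes
#' for the true fold and each control fold.
#'
#' @param n_subjects Cohort size (default 30).
#' @param seed Base seed; subject i uses `seed * 1000 + i`.
#' @param n_trials Trials per subject (default 40; scales runtime).
#' @param folds Symmetry folds to test (default `c(4, 5, 6, 7, 8)`).
#' @param modulation_amplitude,noise_sd Ground-truth signal and noise.
#' @param true_orientation_deg Shared ground-truth orientation.
#' @param detect Run the saccade detector (default `TRUE`).
#' @return List: `median_error_deg`, `errors_deg`, `group_tests` (data
#'   frame fold x p/V/d), `magnitudes` (subject x fold matrix).
#' @export
recovery_study <- function(n_subjects = 30L, seed = 1L, n_trials = 40L,
                           folds = c(4L, 5L, 6L, 7L, 8L),
                           modulation_amplitude = 0.5, noise_sd = 1,
                           true_orientation_deg = 20, detect = TRUE) {
  errors <- numeric(n_subjects)
  mags <- matrix(NA_real_, n_subjects, length(folds),
                 dimnames = list(NULL, paste0("k", folds)))
  for (i in seq_len(n_subjects)) {
    cfg <- simulation_config(
      seed = seed * 1000L + i, n_trials = n_trials,
      modulation_amplitude = modulation_amplitude, noise_sd = noise_sd,
      true_orientation_deg = true_orientation_deg)
    sub <- simulate_subject(cfg, detect = detect)
    g <- grid_analysis(sub, folds = folds, orders = "forward")
    k0 <- cfg$symmetry_fold
    errors[i] <- abs(circ_diff_deg(g$phi_deg[g$k == k0],
                                   true_orientation_deg, 360 / k0))
    mags[i, ] <- g$magnitude[match(folds, g$k)]
  }
  tests <- do.call(rbind, lapply(seq_along(folds), function(j) {
    wt <- wilcoxon_signed_rank(mags[, j], 0, "greater")
    data.frame(k = folds[j], V = wt$statistic, p = wt$p,
               d = wt$effect_size_d, mean_magnitude = mean(mags[, j]))
  }))
  list(median_error_deg = stats::median(errors), errors_deg = errors,
       group_tests = tests, magnitudes = mags)
}

#' Null calibration of the group-level grid test
#'
#' Simulates replicate groups of subjects with zero directional
#' modulation (`a = 0`), runs the split-half analysis at the 6-fold model
#' (ground-truth saccades, no detection, for speed), applies the group
#' one-tailed signed-rank test per replicate, and reports the rejection
#' rate at `alpha` together with the binomial 95% band around `alpha`.
#'
#' @param n_groups Number of replicate groups (default 200).
#' @param subjects_per_group Subjects per replicate (default 8).
#' @param seed Base seed.
#' @param n_trials Trials per subject (default 20).
#' @param n_voxels ROI size per subject (default 8).
#' @param alpha Test level (default 0.05).
#' @return List: `rejection_rate`, `band` (95% binomial band around
#'   `alpha`), `p_values`, `n_groups`.
#' @export
null_calibration_study <- function(n_groups = 200L, subjects_per_group = 8L,
                                   seed = 1L, n_trials = 20L,
                                   n_voxels = 8L, alpha = 0.05) {
  p_values <- vapply(seq_len(n_groups), function(g) {
    mags <- vapply(seq_len(subjects_per_group), function(i) {
      cfg <- simulation_config(
        seed = (seed + g * 1009L) %% 1000000L * 1000L + i,
        n_trials = n_trials, modulation_amplitude = 0,
        n_voxels = n_voxels, blink_prob_per_trial = 0)
      sub <- simulate_subject(cfg, detect = FALSE)
      grid_analysis(sub, folds = 6L, orders = "forward")$magnitude
    }, 0)
    wilcoxon_signed_rank(mags, 0, "greater")$p
  }, 0)
  rate <- mean(p_values < alpha)
  band <- alpha + c(-1, 1) * stats::qnorm(0.975) *
    sqrt(alpha * (1 - alpha) / n_groups)
  list(rejection_rate = rate, band = band, p_values = p_values,
       n_groups = n_groups)
}
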