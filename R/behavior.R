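#' Score recognition responses into hit/miss/FA/CR counts
#'
#' Test-phase rows of the response table are classified by `status`
#' (old/new) crossed with the binned rating: ratings in `old_ratings`
#' count as "old" judgements, ratings in `new_ratings` as "new".
#' Unanswered trials (`NA` rating) are excluded from the counts and
#' reported in `n_unanswered`.
#'
#' @param table Response table with columns `trial_id`, `phase`
#'   (`study`/`test`), `status` (`old`/`new`), `rating`, `stim_id`.
#' @param old_ratings,new_ratings Disjoint integer sets covering the
#'   rating scale (e.g. 1:3 and 4:6 on the 6-point scale, 1:2 and 3:4 on
#'   the 4-point scale).
#' @return List of counts: `n_hits`, `n_misses`, `n_fa`, `n_cr`,
#'   `n_signal`, `n_noise`, `n_unanswered`.
#' @export
bin_responses <- function(table, old_ratings, new_ratings) {
  if (length(intersect(old_ratings, new_ratings)) > 0L)
    stopf("old_ratings and new_ratings must be disjoint")
  scale <- sort(c(old_ratings, new_ratings))
  test <- table[table$phase == "test", , drop = FALSE]
  answered <- test[!is.na(test$rating), , drop = FALSE]
  bad <- !(answered$rating %in% scale)
  if (any(bad))
    stopf("rating outside the scale for trial(s): %s",
          paste(answered$trial_id[bad], collapse = ", "))
  said_old <- answered$rating %in% old_ratings
  is_old <- answered$status == "old"
  list(n_hits = sum(is_old & said_old),
       n_misses = sum(is_old & !said_old),
       n_fa = sum(!is_old & said_old),
       n_cr = sum(!is_old & !said_old),
       n_signal = sum(is_old),
       n_noise = sum(!is_old),
       n_unanswered = sum(is.na(test$rating)))
}

#' Signal-detection d-prime with correction variants
#'
#' Computes d' = z(H) - z(F) from hit/false-alarm counts. With
#' `correction = "loglinear"` 0.5 is added to the hit and false-alarm
#' counts and 1 to the signal and noise trial counts. With
#' `correction = "proportional"` the additions are proportional to the
#' signal:noise composition of the test list (defaults `hit_add = 0.7`,
#' `fa_add = 0.3`, denominators incremented by `2 * hit_add` and
#' `2 * fa_add`), appropriate for designs with twice as many old as new
#' items. With `correction = "none"` raw rates are used and must lie
#' strictly inside (0, 1).
#'
#' @param n_hits,n_fa,n_signal,n_noise Non-negative counts with
#'   `n_hits <= n_signal`, `n_fa <= n_noise`.
#' @param correction `"loglinear"`, `"proportional"`, or `"none"`.
#' @param hit_add,fa_add Proportional-correction increments.
#' @return List: counts, corrected `hit_rate` and `fa_rate`, `z_hit`,
#'   `z_fa`, `d_prime`, `criterion_c`, and the correction name.
#' @export
dprime <- function(n_hits, n_fa, n_signal, n_noise,
                   correction = c("loglinear", "proportional", "none"),
                   hit_add = 0.7, fa_add = 0.3) {
  correction <- match.arg(correction)
  for (nm in c("n_hits", "n_fa", "n_signal", "n_noise"))
    check_number(get(nm), nm, lower = 0)
  if (n_hits > n_signal) stopf("n_hits exceeds n_signal")
  if (n_fa > n_noise) stopf("n_fa exceeds n_noise")
  if (correction == "loglinear") {
    H <- (n_hits + 0.5) / (n_signal + 1)
    FA <- (n_fa + 0.5) / (n_noise + 1)
  } else if (correction == "proportional") {
    H <- (n_hits + hit_add) / (n_signal + 2 * hit_add)
    FA <- (n_fa + fa_add) / (n_noise + 2 * fa_add)
  } else {
    H <- n_hits / n_signal
    FA <- n_fa / n_noise
    if (H <= 0 || H >= 1 || FA <= 0 || FA >= 1)
      stopf(paste("hit or false-alarm rate of 0 or 1 makes d' indeterminate;",
                  "use the 'loglinear' or 'proportional' correction"))
  }
  zh <- stats::qnorm(H)
  zf <- stats::qnorm(FA)
  list(n_hits = n_hits, n_misses = n_signal - n_hits, n_fa = n_fa,
       n_cr = n_noise - n_fa, n_signal = n_signal, n_noise = n_noise,
       hit_rate = H, fa_rate = FA, z_hit = zh, z_fa = zf,
       d_prime = zh - zf, criterion_c = -(zh + zf) / 2,
       correction = correction)
}

#' Label study trials by subsequent memory
#'
#' A study trial is a "hit" iff its linked test response falls in
#' `old_ratings` (i.e. the scene was later recognized), else a "miss".
#'
#' @param study_trials Data frame with `trial_id` and `stim_id`.
#' @param test_table Response table rows (`phase == "test"` used) with
#'   `stim_id`, `status`, `rating`.
#' @param old_ratings Ratings counted as "old" judgements.
#' @return `study_trials` with an added `memory` column (`hit`/`miss`).
#' @export
label_subsequent_memory <- function(study_trials, test_table, old_ratings) {
  test <- test_table[test_table$phase == "test" & test_table$status == "old", ,
                     drop = FALSE]
  idx <- match(study_trials$stim_id, test$stim_id)
  if (anyNA(idx))
    stopf("study trials without a linked test response: %s",
          paste(study_trials$stim_id[is.na(idx)], collapse = ", "))
  study_trials$memory <- ifelse(test$rating[idx] %in% old_ratings,
                                "hit", "miss")
  study_trials
}
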