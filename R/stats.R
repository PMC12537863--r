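#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetrically distributed around `mu`. Exact
#' sign-enumeration p-values are used for n <= 25 when there are no ties
#' among the absolute deviations; otherwise the normal approximation with
#' tie correction is used. Values exactly equal to `mu` are dropped first.
#'
#' @param values Numeric vector.
#' @param mu Null location (default 0).
#' @param alternative `"greater"` (default, the directional hypothesis for
#'   grid magnitudes), `"less"`, or `"two.sided"`.
#' @return List: `statistic_name` (`"V"`), `statistic`, `p`, `tails`,
#'   `effect_size_d`, `n`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  values <- values[values != mu]
  n <- length(values)
  if (n < 1L) stopf("all values equal mu; signed-rank test undefined")
  tied <- anyDuplicated(abs(values - mu)) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    values, mu = mu, alternative = alternative,
    exact = (n <= 25L && !tied), correct = TRUE))
  d <- if (n >= 2L && stats::sd(values) > 0) effect_size_d(values, mu)
       else NA_real_
  list(statistic_name = "V", statistic = unname(wt$statistic),
       p = wt$p.value, tails = alternative, effect_size_d = d, n = n)
}

#' Cohen's d for a one-sample comparison
#'
#' `(mean(values) - mu) / sd(values)` with the n-1 denominator SD.
#'
#' @param values Numeric vector, length >= 2, nonzero SD.
#' @param mu Reference value.
#' @return Cohen's d.
#' @export
effect_size_d <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stopf("need at least 2 values for Cohen's d")
  s <- stats::sd(values)
  if (s == 0) stopf("zero standard deviation; Cohen's d undefined")
  (mean(values) - mu) / s
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' @param x,y Numeric vectors, n >= 4, nonzero variance.
#' @return List: `r`, `ci` (95%, Fisher z +/- 1.96/sqrt(n-3)), `p`
#'   (two-tailed, t with n-2 df), `n`, `degenerate` (TRUE when |r| = 1 and
#'   the CI collapses).
#' @export
pearson_with_ci <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("need n >= 4 for the correlation CI")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  degenerate <- abs(r) >= 1 - 1e-12
  ci <- if (degenerate) c(r, r) else as.numeric(ct$conf.int)
  list(r = r, ci = ci, p = ct$p.value, n = n, degenerate = degenerate)
}

#' Paired or Welch two-sample mean comparison
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param mode `"paired"` or `"welch"`.
#' @param alternative Passed to [stats::t.test()]; two-tailed default.
#' @return List: `statistic_name` (`"t"`), `statistic`, `df`, `p`,
#'   `tails`, `effect_size_d`, `ci` (95% CI of the mean difference), `n`.
#' @export
mean_comparison <- function(values_a, values_b, mode = c("paired", "welch"),
                            alternative = "two.sided") {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(values_a) != length(values_b))
      stopf("paired comparison needs equal-length samples")
    dif <- values_a - values_b
    if (length(dif) < 2L) stopf("need at least 2 pairs")
    if (stats::sd(dif) == 0)
      stopf("zero variance of the paired differences")
    tt <- stats::t.test(values_a, values_b, paired = TRUE,
                        alternative = alternative)
    d <- mean(dif) / stats::sd(dif)
    n <- length(dif)
  } else {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stopf("each group needs at least 2 values")
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
      stopf("zero variance in both groups")
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE,
                        alternative = alternative)
    sp <- sqrt((stats::var(values_a) + stats::var(values_b)) / 2)
    d <- (mean(values_a) - mean(values_b)) / sp
    n <- length(values_a) + length(values_b)
  }
  list(statistic_name = "t", statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, tails = alternative,
       effect_size_d = d, ci = as.numeric(tt$conf.int), n = n)
}

#' Median +/- c * MAD outlier filter
#'
#' Keeps values within `c` raw median-absolute-deviations of the median
#' (no 1.4826 consistency scaling). When MAD is 0, any value deviating
#' from the median is excluded. Applied exactly once; the filter is not
#' idempotent and is not re-run on its own output.
#'
#' @param values Numeric vector, n >= 3.
#' @param c Multiplier (default 3).
#' @return List: `retained` values, `excluded_idx` (indices into the
#'   input), `bounds`.
#' @export
mad_outlier_filter <- function(values, c = 3) {
  if (length(values) < 3L) stopf("need at least 3 values")
  med <- stats::median(values)
  mad0 <- stats::median(abs(values - med))
  keep <- abs(values - med) <= c * mad0
  list(retained = values[keep], excluded_idx = which(!keep),
       bounds = c(med - c * mad0, med + c * mad0))
}

#' Bonferroni-corrected alpha threshold
#'
#' @param alpha Nominal level.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  check_number(m, "m", lower = 1)
  alpha / m
}

#' Chi-square test for directional bias of saccade durations
#'
#' Sums saccade durations within equal-width direction bins on [0, 360)
#' and tests the per-bin totals against a uniform expectation
#' (grand total / `n_bins`) with a chi-square goodness-of-fit statistic
#' (df = `n_bins` - 1). Total time-in-direction is what biases the
#' quadrature regression, hence durations rather than counts are
#' aggregated; each squared deviation is scaled by the duration-weighted
#' mean `sum(d^2)/sum(d)` so the statistic stays chi-square calibrated
#' under uniform directions and reduces exactly to the Pearson count
#' statistic for unit durations.
#'
#' @param saccades Data frame with `direction_deg` and `duration_ms`.
#' @param n_bins Number of direction bins (default 12, i.e. 30-degree
#'   bins).
#' @return List: `statistic`, `df`, `p`, `bin_totals`.
#' @export
direction_bias_test <- function(saccades, n_bins = 12L) {
  if (nrow(saccades) < 1L) stopf("no saccades to test")
  bins <- floor(wrap_deg(saccades$direction_deg) / (360 / n_bins)) + 1L
  d <- saccades$duration_ms
  totals <- vapply(seq_len(n_bins), function(b) sum(d[bins == b]), 0)
  grand <- sum(totals)
  if (grand <= 0) stopf("zero total saccade duration")
  expected <- grand / n_bins
  wbar <- sum(d^2) / grand
  x2 <- sum((totals - expected)^2 / (expected * wbar))
  list(statistic = x2, df = n_bins - 1L,
       p = stats::pchisq(x2, n_bins - 1L, lower.tail = FALSE),
       bin_totals = totals)
}

#' Iterative random exclusion to balance saccade durations
#'
#' While the directional duration-bias test rejects (p <= `alpha`),
#' uniformly at random drops `drop_fraction` of the remaining saccades,
#' re-testing after each pass. Deterministic given `seed`.
#'
#' @param saccades Saccade table (see [direction_bias_test()]).
#' @param drop_fraction Fraction removed per iteration (default 0.10).
#' @param alpha Bias-test level to reach (default 0.05).
#' @param max_iter Iteration cap.
#' @param seed RNG seed for the random exclusions.
#' @param n_bins Direction bins for the bias test.
#' @param min_saccades Abort if the subset falls below this size.
#' @return List: `saccades` (retained subset), `iterations`, `log` (data
#'   frame of per-iteration p-values and counts).
#' @export
rebalance_saccade_durations <- function(saccades, drop_fraction = 0.10,
                                        alpha = 0.05, max_iter = 100L,
                                        seed = 1L, n_bins = 12L,
                                        min_saccades = 30L) {
  cur <- saccades
  log <- data.frame(iteration = integer(0), n = integer(0), p = numeric(0))
  done <- FALSE
  n_iter <- 0L
  with_seed(seed, {
    for (it in 0:max_iter) {
      p <- direction_bias_test(cur, n_bins)$p
      log <- rbind(log, data.frame(iteration = it, n = nrow(cur), p = p))
      if (p > alpha) {
        done <- TRUE
        n_iter <- it
        break
      }
      if (it == max_iter)
        stopf("rebalancing did not converge in %d iterations (last p = %g)",
              max_iter, p)
      n_drop <- ceiling(drop_fraction * nrow(cur))
      if (nrow(cur) - n_drop < min_saccades)
        stopf("rebalancing would drop below %d saccades (currently %d)",
              min_saccades, nrow(cur))
      cur <- cur[-sample.int(nrow(cur), n_drop), , drop = FALSE]
    }
  })
  stopifnot(done)
  list(saccades = cur, iterations = n_iter, log = log)
}
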