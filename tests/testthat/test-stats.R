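test_that("signed-rank test matches exact sign enumeration", {
  w <- wilcoxon_signed_rank(1:5, 0, "greater")
  expect_identical(unname(w$statistic), 15)
  expect_equal(w$p, 1 / 32)
  expect_equal(wilcoxon_signed_rank(3, 0, "greater")$p, 0.5)
  # random small samples against the enumeration oracle
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    v <- round(rnorm(n), 3)
    v <- v[v != 0]
    if (length(v) < 2 || anyDuplicated(abs(v))) next
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(wilcoxon_signed_rank(v, 0, alt)$p,
                   enumerate_signed_rank(v, 0, alt), tolerance = 1e-12)
    }
    # sign-flip symmetry
    expect_equal(wilcoxon_signed_rank(v, 0, "greater")$p,
                 wilcoxon_signed_rank(-v, 0, "less")$p, tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(rep(2, 5), 2), "equal mu")
})

test_that("Cohen's d is the mean over the n-1 SD and is scale invariant", {
  expect_equal(effect_size_d(c(1, -1)), 0)
  expect_equal(effect_size_d(c(0, 2)), 1 / sqrt(2))
  set.seed(3)
  x <- rnorm(20, 1)
  expect_equal(effect_size_d(3.7 * x), effect_size_d(x))
  expect_error(effect_size_d(rep(1, 5)), "zero standard deviation")
})

test_that("Pearson correlation carries a Fisher-transform CI", {
  set.seed(4)
  x <- rnorm(30)
  r1 <- pearson_with_ci(x, x)
  expect_equal(r1$r, 1)
  expect_true(r1$degenerate)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  y <- 0.5 * x + rnorm(30, 0, 1)
  res <- pearson_with_ci(x, y)
  z <- atanh(res$r)
  expect_equal(res$ci, tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(30 - 3)),
               tolerance = 1e-10)
  expect_true(res$ci[1] <= res$r && res$r <= res$ci[2])
  expect_error(pearson_with_ci(x[1:3], y[1:3]), "n >= 4")
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("null p-values of the correlation are uniform", {
  set.seed(5)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i)
    pearson_with_ci(rnorm(20), rnorm(20))$p, 0)
  rate <- mean(p < 0.05)
  band <- qnorm(0.975) * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), band + 1e-12)
})

test_that("mean comparisons match hand formulas", {
  a <- c(4.1, 5.2, 3.3, 6.0, 5.5)
  b <- c(2.0, 3.1, 2.7, 4.4, 3.3, 2.2, 3.9)
  res <- mean_comparison(a, b, "welch")
  se <- sqrt(var(a) / 5 + var(b) / 7)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 7)^2 / 6)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  # paired with a constant offset plus jitter recovers the offset
  set.seed(6)
  x <- rnorm(10)
  res_p <- mean_comparison(x + 0.8 + rnorm(10, 0, 1e-6), x, "paired")
  expect_equal(mean(res_p$ci), 0.8, tolerance = 1e-3)
  expect_error(mean_comparison(x, x, "paired"), "zero variance")
})

test_that("MAD filter implements the raw median +/- 3 MAD rule", {
  v <- c(1:9, 100)
  f <- mad_outlier_filter(v)
  expect_equal(f$bounds, c(-2, 13))
  expect_identical(f$excluded_idx, 10L)
  expect_equal(f$retained, 1:9, ignore_attr = TRUE)
  all_eq <- mad_outlier_filter(rep(7, 5))
  expect_identical(length(all_eq$retained), 5L)
  # MAD 0 with deviants: deviants excluded
  f0 <- mad_outlier_filter(c(rep(2, 6), 2.5))
  expect_identical(f0$excluded_idx, 7L)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
})

test_that("duration-bias test is calibrated and detects concentration", {
  # one saccade per bin with equal durations: exactly uniform
  sac <- data.frame(direction_deg = seq(15, 345, by = 30), duration_ms = 30)
  res <- direction_bias_test(sac)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # everything in one bin: overwhelming bias
  sac1 <- data.frame(direction_deg = rep(10, 400), duration_ms = 30)
  expect_lt(direction_bias_test(sac1)$p, 1e-10)
  # null calibration with realistic duration spread
  set.seed(7)
  reps <- 1000
  p <- vapply(seq_len(reps), function(i) {
    s <- data.frame(direction_deg = runif(300, 0, 360),
                    duration_ms = runif(300, 20, 60))
    direction_bias_test(s)$p
  }, 0)
  rate <- mean(p < 0.05)
  band <- qnorm(0.975) * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), band + 0.01)
})

test_that("rebalancing terminates, is seed-stable, and is a no-op when unbiased", {
  set.seed(8)
  fair <- data.frame(direction_deg = runif(400, 0, 360),
                     duration_ms = runif(400, 20, 60))
  res <- rebalance_saccade_durations(fair, seed = 1)
  expect_identical(res$iterations, 0L)
  expect_identical(nrow(res$saccades), 400L)
  # strongly biased: half the time budget in one 30-degree sector
  biased <- rbind(fair,
                  data.frame(direction_deg = runif(45, 0, 30),
                             duration_ms = runif(45, 40, 60)))
  res_b <- rebalance_saccade_durations(biased, seed = 2)
  expect_gt(res_b$iterations, 0L)
  expect_gt(direction_bias_test(res_b$saccades)$p, 0.05)
  expect_true(all(diff(res_b$log$n) <= 0))
  res_b2 <- rebalance_saccade_durations(biased, seed = 2)
  expect_identical(res_b$saccades, res_b2$saccades)
  res_b3 <- rebalance_saccade_durations(biased, seed = 3)
  expect_false(identical(res_b$saccades, res_b3$saccades))
})
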