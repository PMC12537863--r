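# shared fixtures, built once per test run

fixture_env <- new.env()

small_config <- function(seed = 42L, n_trials = 30L, ...) {
  simulation_config(seed = seed, n_trials = n_trials, ...)
}

# a default-noise simulated subject with detection applied (cached)
fixture_subject <- function() {
  if (is.null(fixture_env$subject))
    fixture_env$subject <- simulate_subject(small_config())
  fixture_env$subject
}

# noiseless world for identifiability checks: BOLD generated from a chosen
# saccade subset only
noiseless_config <- function(seed = 42L, ...) {
  simulation_config(seed = seed, n_trials = 30L, noise_sd = 0,
                    drift_amplitude = 0, blink_prob_per_trial = 0, ...)
}

# independent sign-enumeration oracle for the signed-rank test
enumerate_signed_rank <- function(values, mu = 0,
                                  alternative = "greater") {
  v <- values[values != mu]
  n <- length(v)
  r <- rank(abs(v - mu))
  V <- sum(r[v > mu])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  allV <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(allV >= V),
         less = mean(allV <= V),
         two.sided = min(1, 2 * min(mean(allV >= V), mean(allV <= V))))
}

# brute-force normal-equation GLM oracle
solve_normal_equations <- function(X, Y) {
  solve(t(X) %*% X, t(X) %*% Y)
}
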