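# shared cohort definition for the analysis scripts: 12 simulated subjects
# under the default study conditions, scaled to 40 trials for desk-size runs
library(gridgaze)

COHORT_SEED <- 2026L
N_SUBJECTS <- 12L

cohort_config <- function(i, ...) {
  simulation_config(seed = COHORT_SEED * 1000L + i, n_trials = 40L, ...)
}

simulate_cohort <- function(n = N_SUBJECTS, ...) {
  lapply(seq_len(n), function(i) simulate_subject(cohort_config(i, ...)))
}

dir.create("results", showWarnings = FALSE)
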