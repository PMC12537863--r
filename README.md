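# gridgaze

Saccade-based grid-like code analysis for eye-tracking and fMRI data.

Entorhinal grid cells fire on the vertices of a hexagonal lattice, and a
population signal driven by movement direction inherits a six-fold
(hexadirectional) modulation. During free viewing of scenes, saccade
direction plays the role of movement direction: a region-of-interest
BOLD signal may respond more strongly to saccades aligned with the
subject's grid orientation. `gridgaze` implements the full estimation
chain for cognitive-neuroimaging researchers who want to run, probe, or
stress-test this analysis:

- **Saccade detection** from raw gaze traces: velocity-threshold
  detection (6 × SD of the velocity distribution, duration > 12 ms,
  25 ms preceding fixation), blink detection from pupil deviations, and
  the study-specific exclusion rules (blink pads, adjacent-saccade pads,
  25%-missing-data trial rejection), bundled as `donders`/`vienna`
  profiles.
- **Recognition-memory scoring**: hit/miss/FA/CR binning on 6- or
  4-point confidence scales and d′ = z(H) − z(F) with log-linear
  (+0.5/+1) and proportional (+0.7/+0.3) corrections, plus
  subsequent-memory (hit vs. miss) trial labels.
- **GLM machinery**: canonical double-gamma HRF, stick/boxcar
  regressors with mean-centered parametric modulators at 16 microtime
  bins per TR, 18-column motion nuisance expansion, 128 s discrete-cosine
  high-pass basis, and mass-univariate OLS.
- **The two-stage grid-code analysis**: split each run into two halves;
  estimate the grid orientation from quadrature modulators sin(kα),
  cos(kα) as φ̂ = atan2(mean β₁, mean β₂)/k; test alignment of the
  held-out saccades with a cos[k(α − φ̂)] modulator; repeat for control
  symmetries k ∈ {4,5,7,8}, both partition orders, and
  condition-specific (hits/misses) variants; derive trial-wise grid
  values and the trial-modulation GLM.
- **Group statistics**: one-tailed Wilcoxon signed-rank tests with
  Cohen's d, Pearson correlations with Fisher CIs, median ± 3 MAD
  outlier exclusion, Bonferroni thresholds, and the directional
  duration-bias diagnostic with iterative 10% random saccade dropping.
- **A synthetic-data generator** that emulates the paradigm end to end
  (trial-structured gaze with injected saccades and blinks,
  signal-detection behavior, BOLD with a known k-fold modulation of
  amplitude *a* around orientation φ₀) so every stage can be validated
  against ground truth.

See `vignettes/saccade-grid-codes.Rmd` for the model, the estimation
assumptions, and the design decisions.

## Worked example

Simulate a subject under the default study conditions (200 scene trials
scaled here to 40; 6-fold modulation, a = 0.5, φ₀ = 20°, BOLD noise
SD 1), detect its saccades, and run the split-half analysis:

```r
library(gridgaze)

cfg <- simulation_config(seed = 3, n_trials = 40)
sub <- simulate_subject(cfg)          # gaze -> detection -> behavior -> BOLD
nrow(sub$saccades)                    # retained, trial-linked saccades
#> [1] 237
sub$behavior_summary$d_prime          # log-linear corrected d'
#> [1] 2.019465

g <- grid_analysis(sub, folds = c(4L, 5L, 6L, 7L, 8L), orders = "forward")
g[g$k == 6, c("k", "phi_deg", "magnitude")]
```

The orientation estimate lands on the ground truth and the alignment
magnitude on the generating amplitude; the control symmetries carry
nothing. The cohort-level drivers under `analysis/` print, for 12
simulated subjects (`Rscript analysis/04_gridcode.R`,
`Rscript analysis/05_group.R`):

```
Median |phi_hat - phi0| in 60-degree space: 0.66 degrees (n = 12).
Mean 6-fold magnitude 0.499 (forward), 0.497 (reversed); control folds -0.004.
6-fold forward: mean 0.491 +/- 0.014 (SEM), V = 45, one-tailed p = 0.001953, d = 12.05.
Bonferroni threshold across 5 folds: 0.010.
Control folds: 8/8 cells with p > 0.05.
```

That is: orientations are recovered to well under a degree, the held-out
alignment beta reproduces the generating amplitude a = 0.5, the group
signed-rank test is decisive for the 6-fold model only, and reversing
the partition changes nothing — the same pattern of results the analysis
is designed to detect on real data. The numbered scripts in `analysis/`
(`01_simulate` … `05_group`) walk through simulation, detection
validation, behavioral scoring, the grid analysis, and group inference,
writing tidy tables under `results/`.

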