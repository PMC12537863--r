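---
title: "Saccade-based grid-like codes: model, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccade-based grid-like codes: model, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The signal model

Grid cells in the entorhinal cortex fire on the vertices of a hexagonal
lattice, and population measurements inherit a six-fold directional
signature: a signal driven by movement (here, saccadic eye movement)
direction $\alpha$ is modulated as

$$ y \propto 1 + a\,\cos\!\left[k(\alpha - \varphi)\right], \qquad k = 6, $$

where $\varphi$ is the *grid orientation* (defined modulo $360/k$
degrees) and $a$ the modulation amplitude ("grid magnitude"). In fMRI
the directional drive is observed only after convolution with the
hemodynamic response, so the analysis is cast as a GLM over the BOLD
time series with saccade-onset stick functions and directional
parametric modulators. Control symmetries $k \in \{4, 5, 7, 8\}$ share
the machinery and should carry no signal if the six-fold model is the
right one.

## Two-stage cross-validated estimation

Estimating $\varphi$ and testing alignment on the same data would be
circular, so the analysis splits each subject's run into two
contiguous-in-time halves at the trial midpoint (odd trial counts give
the extra trial to the estimation half):

1. **Orientation estimation.** Saccades of the estimation half enter as
   sticks with two mean-centered parametric modulators,
   $\sin(k\alpha_t)$ and $\cos(k\alpha_t)$; the held-out half's saccades
   enter unmodulated. With voxelwise OLS betas $\beta_1$ (sin) and
   $\beta_2$ (cos), the ROI orientation is
   $\hat\varphi = \operatorname{atan2}(\overline{\beta_1},
   \overline{\beta_2})/k$, wrapped into $[0, 360/k)$. The two-argument
   arctangent is used deliberately: the plain arctangent of the beta
   ratio is quadrant-ambiguous, and the quadrant-aware form is validated
   in the tests against a brute-force grid-search oracle. Voxel betas
   are averaged *before* the arctangent (the ROI-mean formula), not
   circularly averaged per voxel.
2. **Alignment test.** A second GLM leaves the estimation half
   unmodulated and gives the test half's saccades a single mean-centered
   modulator $\cos[k(\alpha_t - \hat\varphi)]$. The ROI-mean beta of
   this modulator is the grid magnitude; it is positive when held-out
   saccades aligned with $\hat\varphi$ evoke stronger responses. Both
   partition orders (estimate-on-first/test-on-second and the reverse)
   are run; reversing the roles is a built-in robustness check.

Both GLMs include: the other-half stick regressor, 18 motion nuisance
columns (6 realignment parameters, their first derivatives, and squared
derivatives), a discrete-cosine high-pass basis with a 128 s cutoff, and
an intercept. The DCT basis itself contains a constant column; the GLM
assembly drops that column and keeps one explicit intercept, otherwise
the design would be rank deficient.

Condition-specific variants (subsequently remembered "hit" trials
vs. forgotten "miss" trials) restrict the *modulated* test saccades to
the condition's trials while the estimation step always uses all trials
of the estimation half — miss trials are typically too few to estimate
an orientation on their own.

Trial-wise grid values are the per-saccade alignment
$\cos[k(\alpha - \hat\varphi)]$ averaged within a trial, with
$\hat\varphi$ always taken from the opposite half (both partition orders
concatenated so every trial is covered). By default the per-saccade value
is the unit-amplitude cosine, *not* scaled by the alignment-GLM beta;
beta scaling would not change trial rank order within a subject and is
left to the caller. These trial values feed a third GLM (4 s boxcar per
scene trial, mean-centered trial-value modulator) whose per-voxel
modulator beta is the subject-level contrast used for group inference;
cluster-level corrected whole-brain inference is out of scope here.

## Saccade detection and exclusion

Saccades are detected from 2-D gaze velocity (5-sample central
difference by default; the differencing window is configurable) as
maximal suprathreshold runs with duration strictly greater than 12 ms,
preceded by at least 25 ms of subthreshold, non-missing samples. The
threshold is 6 times the SD of the velocity distribution of the whole
recording. Two SD estimators are available:

* `"median"` (default): the median-based robust estimator per axis with
  an elliptic criterion — the estimator used by the velocity-threshold
  algorithm standard in the eye-movement literature and implemented in
  the toolboxes this field uses. It is insensitive to the saccadic
  samples themselves.
* `"moment"`: the plain SD of the pooled speed distribution. Because
  saccades contribute most of the velocity *variance* despite occupying
  a small fraction of samples, this estimator places the threshold above
  the peak velocity of small (2 degree) saccades and misses them; it is
  provided for comparison, not recommended.

Blinks are pupil-deviation events (mean ± 5 SD for the 1000 Hz
profile, ± 1 SD for the other), with missing pupil samples counted as
blink samples and runs closer than 2 samples merged. Exclusion rules are
profile-bound: saccades within ±100 ms of a blink (or ±300 ms, plus
±100 ms of a neighbouring saccade, in the second profile) are excluded,
and all saccades of a trial whose gaze samples are more than 25% missing
are discarded. Missing samples break suprathreshold runs — a saccade
cannot span a gap.

Angles use a fixed convention: 0° rightward on screen, counter-clockwise
positive in the mathematical (y-up) frame, range $[0, 360)$. Grid
results are invariant to this choice up to a constant rotation of
$\varphi$ (tested as a rotational-equivariance property).

## Behavior: signal-detection scoring

Recognition responses are binned by status × rating (6-point scale:
"old" = ratings 1–3; 4-point scale: "old" = ratings 1–2) and summarized
by $d' = z(H) - z(F)$ with exact normal quantiles. Two corrections for
extreme rates are provided: log-linear (add 0.5 to hits and false
alarms, 1 to signal and noise counts) and proportional (defaults 0.7 /
0.3 and twice those in the denominators, matching a 2:1 old:new test
composition). Unanswered trials are excluded from the counts and
reported in a QC field. With `correction = "none"`, rates of 0 or 1 are
an error that recommends a correction.

## Group statistics

Grid magnitudes are tested against zero with a one-tailed (greater)
Wilcoxon signed-rank test — the directional hypothesis — with exact
p-values for $n \le 25$ without ties and the tie-corrected normal
approximation otherwise, Cohen's $d = \bar{x}/s$ as effect size, and a
Bonferroni threshold $\alpha/m$ across ROIs or symmetries. Before
testing, values outside median ± 3 × MAD are excluded; the MAD is raw
(no 1.4826 consistency constant), the filter is applied exactly once,
and re-filtering is deliberately not done (the rule is not idempotent).
Correlations (e.g. magnitude vs. $d'$ or hit rate) are Pearson with a
Fisher-transform 95% CI.

The directional duration-bias diagnostic sums saccade durations within
twelve 30° bins and compares the totals to a uniform expectation.
A plain Pearson statistic on millisecond totals scales with the mean
duration and is not chi-square distributed, so each squared deviation is
scaled by the duration-weighted mean $\sum d_i^2 / \sum d_i$; the
statistic then reduces exactly to the Pearson count statistic for unit
durations and its null rejection rate sits in the binomial band in the
package's calibration tests. Biased subjects are handled by iteratively
dropping a uniformly random 10% of saccades until the bias test clears
$p > 0.05$ (seed-reproducible; uniform dropping, not targeted, matching
the random-exclusion procedure; guarded by the 30-saccade floor).

## The synthetic-data generator

Real recordings of this paradigm are not publicly distributable, so
validation runs on synthetic subjects with known ground truth. The
generator emulates: 200 scene trials of 4 s with inter-trial intervals
of 2.125/4.125/7.125 s in an 80:80:40 ratio; 1000 Hz gaze on a
1280 × 960 px screen (36.9 × 27.7 cm at 86.6 cm); Poisson saccade counts
(mean 7.58/trial), amplitudes uniform on 2–10°, raised-cosine position
profiles, fixation jitter (SD 0.5 px), blinks as pupil dropouts with
missing positions; an equal-variance signal-detection response model
($d' = 1.82$, criterion at $d'/2$); and BOLD at TR = 0.657 s from a
25-voxel ROI whose neural impulse at each saccade onset has height
$1 + a\cos[k(\alpha - \varphi_0)]$, convolved with the canonical
double-gamma HRF, plus white Gaussian voxel noise, a random linear
drift, a baseline of 100, and six slow-random-walk motion traces.

Choices worth flagging:

* **Saccade durations follow a main-sequence-like rule**
  (≈ 21 ms + 2.2 ms/deg, ± 2 ms). Durations drawn independently of
  amplitude would give small saccades implausibly low peak velocities
  and make the detector's documented closure guarantee (precision and
  recall ≥ 0.95) unattainable; the coupling is also what real saccades
  do. The raised-cosine profile is a kinematic convenience — only
  onsets and directions matter downstream.
* **Noise is white per voxel by default.** No autocorrelation model is
  fitted in the GLMs (OLS only), so the generator's default matches the
  estimator's assumption; an AR(1) option (`ar1_phi`) exists for
  sensitivity checks. This is a documented limitation: on real data,
  serial correlation inflates test statistics at the single-subject
  level, though the group-level signed-rank test only needs
  subject-level exchangeability.
* **Noise amplitude** (`noise_sd = 1` against unit-height impulses) and
  `a = 0.5` are calibration choices, not literature values — no SNR
  figure for entorhinal BOLD at this field strength is available to pin
  them; they are chosen so that a realistic cohort (30 subjects) gives
  clearly detectable but far-from-saturated effects.
* **Memory labels come from the behavioral generator**, so
  condition-specific (hits/misses) grid analyses can be exercised with
  consistent ground truth.
* What the generator does *not* emulate: pink/physiological noise,
  image-space voxel structure, smooth pursuit and microsaccades, and
  eye-tracker drift/calibration error. Passing tests therefore show the
  estimator chain is correct and calibrated under its stated
  assumptions, not that real entorhinal data carry the effect.

## Numerical choices and degenerate inputs

* Events snap to the nearest of 16 microtime bins per TR before HRF
  convolution; volume $i$ is sampled at $i \cdot \mathrm{TR}$ (0-based),
  with no slice-timing offset. The HRF kernel is peak-normalized.
* Parametric modulators are mean-centered, not serially orthogonalized
  against the unmodulated column (exposed as a flag). Centering alone
  leaves the modulator orthogonal to the event envelope in the height
  domain, which is all the alignment logic needs.
* OLS is solved by QR; rank deficiency is an error naming the collinear
  columns rather than a silent pseudo-inverse.
* Orientation is undefined when both mean betas are exactly zero
  (error); a constant trial-value series makes the third GLM's centered
  modulator identically zero (error).
* Tie-breaks: boundary samples between two candidate velocity runs
  belong to the earlier run; the estimation half receives the extra
  trial on odd splits.
* The ROI voxel-quality score defaults to relative mean intensity
  (voxel temporal mean over the grand mean of voxel means) with
  threshold 0.8 and a 14-voxel minimum; a tSNR variant is selectable.
  The quality metric is configurable precisely because "signal-to-noise
  threshold of 0.8" admits more than one reading — a tSNR of 0.8 would
  be implausibly low for any usable voxel.

## Validation studies and problem sizes

The packaged validation suite (also reproduced by
`scripts/acceptance.R`) uses cohort sizes chosen to make the studies
sharp but desk-sized: a 30-subject recovery cohort at 40 trials/subject
(median circular orientation error well under 5° in 60°-space; group
one-tailed signed-rank $p < 0.05$ at $k = 6$ and $p > 0.05$ at the
control folds), and 200 replicate null groups of 8 subjects at 20
trials (rejection rate at $\alpha = 0.05$ inside the binomial 95%
band). Exact identities — noiseless orientation recovery to $10^{-6}$
degrees, alignment beta equal to $a$, GLM coefficients against a
normal-equation solve, signed-rank p-values against full sign
enumeration — are tested at machine-level tolerances. One caveat on the
noiseless identities: they generate BOLD from the modeled half's
saccades only, because with both halves modulated but only one modeled
parametrically, the held-out half's modulated component leaks a
(tiny, noise-level) bias into the estimation betas; the full-pipeline
recovery study covers the realistic case.

Because control-fold group p-values are uniform under the null, any
single run has a ~5% chance per fold of dipping below 0.05; the
specificity claim is about the ensemble, not any one seed.

## Known limitations

No prewhitening; no slice-timing or physiological-noise modeling; the
split is by trial midpoint (runs/blocks, when present, should be split
within-run and concatenated into one GLM, which is how the two-block
variant is handled); and whole-brain cluster inference is out of scope —
NIfTI input is supported only as ROI extraction (4-D image plus binary
mask to a volumes × voxels matrix), not as image-space analysis.
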