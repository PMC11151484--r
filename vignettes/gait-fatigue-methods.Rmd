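---
title: "Methods: from raw lower-back accelerometry to fatigue associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw lower-back accelerometry to fatigue associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, algorithms, parameter choices and known
limitations behind `gaitfatigue`. The package turns continuous triaxial
acceleration from a sensor at the lower back (L5), recorded at 100 Hz in
units of g over multiple free-living days, plus a diary of momentary
physical-fatigue (PF) and mental-fatigue (MF) scores on a 0-6 Likert scale,
into (i) pooled macro and micro gait features for the 2-h window preceding
each diary entry, (ii) per-feature mixed-model associations with the scores,
and (iii) low/high-fatigue classification under two cross-validation
designs.

## Walking-bout detection

The recording is lowpass filtered (2nd-order Butterworth, 17 Hz cutoff) and
segmented into non-overlapping 0.1-s windows. A window counts as "upright
and moving" when two conditions hold simultaneously:

* the per-axis standard deviations sum to at least 0.05 g
  (`sd_VV + sd_ML + sd_AP >= 0.05`), and
* the mean vertical acceleration is at most -0.77 g.

The second condition is only meaningful on a gravity-retaining signal, so
the window mean is computed on the filtered but *not* mean-normalised
vertical axis, while the SD condition is indifferent to mean removal. Runs
of active windows separated by fewer than 20 inactive windows (2 s) are
merged left to right until no mergeable gap remains; gap lengths never
change during merging, so a single pass over all gaps reaches the fixpoint.
Merged runs shorter than 20 windows are discarded; runs of exactly 20
windows are retained and gaps of exactly 20 windows are not merged (both
rules are strict "less than 20"). Windows overlapping missing data are
inactive by definition and a gap containing missing data is never merged,
so no bout spans a recording gap. The complement of the retained walking
bouts within valid data forms the non-walking bouts; together they
partition the valid recording exactly.

All filtering in the package is zero-phase (forward-backward), so detected
event times carry no filter lag. Orientation errors (sensor worn upside
down) are corrected automatically: any day whose mean vertical acceleration
is positive has all three axes negated, because an upside-down sensor
inverts the vertical and anterior-posterior axes together. The rule is
idempotent and logged per day.

## Step events

Within each walking bout the vertical axis is linearly detrended, mean
normalised, lowpass filtered (4th-order Butterworth, 20 Hz), integrated by
cumulative trapezoid, and differentiated with a Gaussian
continuous-wavelet-transform smoother. Initial contacts (IC) are local
minima of this smoothed signal; final contacts (FC) are local maxima of a
further CWT differentiation. Candidate minima are retained when their depth
reaches 0.4 x the mean candidate depth, maxima at 0.25 x the mean candidate
height, with depths measured relative to the signal mean and an absolute
floor of 1e-8 guarding against numerical-noise extrema on near-constant
segments.

The wavelet family is fixed (first derivative of a Gaussian); the scale is
a tunable parameter defaulting to `sampling_rate / 10` samples (0.1 s at
100 Hz), a smoothing width at step-frequency scale. The scale only affects
peak amplitudes, not symmetric peak positions, so event timing is robust to
it; it is exposed in `detect_ic_fc()` for sensitivity analyses.

Bouts with fewer than three detected steps are removed entirely. The first
three and last five steps of each bout are masked as gait
initiation/termination. Any step with step time at or outside (0.25, 1.25)
s, step length at or outside (0.23, 0.95) m, or swing time at or outside
(0.23, 0.95) s is masked as an outlier. Masking order: bout removal, then
initiation, then outliers; masks only set a validity flag and never reorder
events.

## Micro (step-level) measures

From the ordered IC/FC sequence, with `FC_{i+1}` the next FC after
`IC_{i+1}`:

* stance_i = FC_{i+1} - IC_i
* stride_i = IC_{i+2} - IC_i
* swing_i = stride_i - stance_i (so swing + stance = stride holds exactly)
* step_i = IC_{i+1} - IC_i

Step length uses the inverted-pendulum model, `L = 2 sqrt(2 l h - h^2)`,
with pendulum length `l = 0.53 x body height` and `h` the vertical
excursion of the centre of mass during the step. `h` is the peak-to-trough
of the position signal between consecutive ICs, obtained by double
cumulative-trapezoid integration of the vertical acceleration with a
4th-order 0.1-Hz Butterworth highpass after each integration stage to
suppress drift. Steps with `h >= 2l` fall outside the model's range and get
a missing length; `h >= l` is flagged suspect. Step velocity is step length
over step time.

Foot labels alternate from the first detected step of each bout, which is
assigned to the right foot. Variability of a measure is its SD over the
scope's valid steps; asymmetry is |mean(left) - mean(right)|, which is
invariant to a global label swap — the right quantity given that the
first-step-is-right convention is arbitrary. Both are computed per walking
bout (one value per bout), and the windowing stage pools the per-bout
values; the alternative of pooling all steps of a window into one scope
would hide between-bout structure and is not what a per-bout feature table
supports. The sixteen micro measures are grouped as pace (step velocity,
step length, SD of swing time), rhythm (stance, swing, step, stride time),
variability (SDs of step time, stance time, step velocity, step length,
stride time), asymmetry (step, swing, stance time) and postural control
(step-length asymmetry).

## Macro (activity-level) measures

Walking volume: per-bout valid step counts, walking-bout lengths, number of
walking bouts, number of bouts of 10 min or more. Non-walking volume:
non-walking bout lengths and counts of gaps of at least 20, 30 and 50 min.
Pattern: the power-law alpha parameter of walking-bout lengths
(`alpha = 1 + n / sum(log(x_i / x_min))`, the maximum-likelihood exponent
with `x_min = min(x)`), plus mean walking and mean non-walking time.
Variability: the bout-length variability S2, the maximum-likelihood
lognormal shape (population form, divisor n) of walking (S2W) and
non-walking (S2S) bout lengths — scale-invariant by construction. Vector
magnitude: the per-sample Euclidean norm of the three axes, reported in
m/s^2 (1 g = 9.80665 m/s^2).

Two conventions were genuinely open and are fixed as defaults with a
switch: the vector magnitude is computed over *all* samples of the 2-h
window (`vm_scope = "window"`), since it is an activity measure in its own
right rather than a bout property; `"walking"` restricts it to walking
bouts. And "excluding the mean" for bout-length series means the mean
statistic is dropped from their pooled statistic set, because the same
quantity already appears in the pattern group as mean walking/non-walking
time — keeping both would duplicate a feature.

## Windowing and the modelling table

Each diary entry looks back 2 h; bouts are selected by their *start* time
(a bout beginning inside the window but ending after the entry is included
in full). Multi-valued measures are pooled into nine statistics: mean, SD,
variance, sum, minimum, maximum, median, and the 25th/75th percentiles.
Percentiles interpolate linearly between order statistics (R's `quantile`
type 7); SD and variance use the sample (n-1) form; a single value has SD
and variance 0. A count-of-values statistic exists behind
`include_count = TRUE` but is off by default — the nine above are the
documented set, and inventing a tenth silently would change the feature
space. Scalar measures (bout counts, alpha, S2) pass through tagged
`single`. The default table has 44 macro and 144 micro feature columns,
named `domain__group__measure__statistic`; the micro count follows from
16 bout-level measures x 9 pooled statistics and is configurable through
the statistic set.

A row (feature window) is retained only when at least one walking bout
began in the window *and* at least one of the two scores is present;
subjects with no retained rows drop out of the table entirely. PF and MF
analyses differ only through label missingness, never through features.

## Association screening

Each feature is screened in its own generalised linear mixed model. The
0-6 score is encoded as y successes out of 6 Bernoulli trials with a logit
link — the only encoding that makes a bounded 7-level score
binomial-compatible — with the standardised feature as the single fixed
slope and a subject random intercept; the likelihood is maximised with
adaptive Gauss-Hermite quadrature (10 points). Observations are weighted by
the inverse frequency of their score. The raw weights `1/count(score)` sum
to the number of distinct scores, which would shrink the effective sample
to a handful of observations, so the weights are rescaled to mean 1: the
relative weighting is untouched (a constant rescale) while estimates and
variance components stay on the information scale of n observations.

A caution that matters for interpretation: these weights are functions of
the *outcome*. Simulation in the package's validation suite shows that
outcome-dependent weighting distorts Wald-test calibration under the null —
unweighted fits are calibrated, weighted ones are not — so the p-values of
the default path should be read as descriptive screening scores, not
calibrated error rates. `fit_glmm(weighting = "none")` provides the
calibrated alternative.

Model fit is summarised by the latent-scale variance partition: with `vf`
the variance of the fixed-effect linear predictor, `vr` the random-intercept
variance and `vd = pi^2/3` the logistic distribution-specific variance,
marginal R2 = vf/(vf+vr+vd) and conditional R2 = (vf+vr)/(vf+vr+vd); the
ordering marginal <= conditional holds by construction on every converged
fit. Group and statistic rankings average R2 with statistically significant
(p < 0.05) entries counted twice. No multiple-testing correction is applied
by default (raw p-values are reported); `p.adjust` can be applied to the
screen table by the user.

## Classification

Two designs: intersubject (five-fold leave-subjects-out; labels binarised
0-2 low / 3-6 high) and intrasubject (five-fold CV within each subject;
binarised *after* splitting with the training-score mean as threshold,
score strictly above the mean = high, so a score equal to the mean is low).
Folds whose training or test split lacks a class are skipped and logged.

Per fold, strictly in order: training-median imputation (the median resists
the extreme values these features produce); SMOTE oversampling of the
training minority class to exact parity (synthetic points interpolate
between a minority sample and one of its k = min(5, minority - 1) nearest
minority neighbours); standardisation with post-SMOTE training statistics;
a seeded shuffle. The test split is imputed and scaled with
training-derived parameters only and never resampled — the validation
suite asserts this by poisoning test folds and checking the training-side
outputs bit-for-bit.

Four families are tuned by exhaustive grid search with inner stratified
10-fold CV scored by balanced accuracy: RBF-kernel SVM (cost and gamma over
1e-3..1e3, 49 combinations), kNN (k in 1,2,3,4,5,6,8,10,15), random forest
(trees in 5,10,50,100,200,500 crossed with mtry rules sqrt(N), log2(N), N;
prediction by thresholding the forest's averaged probabilistic vote at
0.5), and Gaussian naive Bayes (no tuned parameter). Degenerate inner folds
score 0 for that combination. Metrics, with high fatigue as the positive
class: precision TP/(TP+FP), recall TP/(TP+FN), balanced accuracy
(sensitivity + specificity)/2; precision is missing when nothing is
predicted positive.

A single run-level seed drives fold shuffles, SMOTE, row shuffles and the
stochastic learners, making a run reproducible end to end.

## Feature importance

The tree ranker trains a gradient-boosted decision-tree ensemble
(`xgboost`; 50 rounds, depth 4, learning rate 0.1 — library-default-style
settings recorded in the function signature) per stratified fold and scores
each feature by its normalised total split gain — the share of the summed
node-impurity decrease over nodes splitting on that feature — averaged over
folds. A feature never split on scores exactly 0 and the shares sum to 1.
Permutation importance is `i_j = s - mean_k(s_kj)` over K = 5 seeded
permutations of feature j, scored by balanced accuracy; a feature the model
provably ignores scores exactly 0. The final permutation ranking averages
the four classifier families.

## The synthetic cohort generator

The study data these methods target are not redistributable, so validation
runs on a generator with complete ground truth. It emulates: a wear day
(default 09:00-23:00) alternating lognormal rest gaps (default median 5
min, sigma 0.75 log-s) and walking bouts with power-law lengths (exponent
1.8 above 10 s, truncated at 1 h so a bout fits a day); per-subject cadence
(1.9 +/- 0.1 steps/s) and step length (0.65 +/- 0.05 m); white sensor noise
(0.005 g per axis); whole-day sensor flips (probability 0.1); contiguous
missing blocks (2% of samples, ~5-min blocks); and four daily diary bins
answered with probability 0.85, each answered entry losing either score
with probability 0.05.

The walking waveform is a fundamental at the instantaneous step frequency
plus a phase-locked first harmonic (quarter amplitude) on the vertical
axis, with phase-shifted copies on the other axes; per-step durations
jitter around the subject's cadence and alternate-step amplitudes encode a
5% left/right step-length asymmetry. The vertical amplitude of each step is
set by inverting the pendulum relation — `h = l - sqrt(l^2 - L^2/4)`, then
amplitude `= h omega^2 / (2 g)` — so the pipeline's double integration
recovers the injected step length; this is what makes end-to-end parameter
recovery a meaningful test. True ICs sit at the waveform minima, which is
exactly where the detector looks, so IC timing errors measure numerical
fidelity rather than model mismatch.

Fatigue scores are Binomial(6, plogis(eta)) draws with eta = population
intercept (qlogis(2.5/6), centring scores near 2.5) + a subject intercept
(SD 1, matching the wide between-subject spread such diaries show) +
coupling_beta x the standardised windowed true gait feature; the binomial
sampling itself supplies the 0-6 discretisation noise, and coupling_beta
defaults to 0 (no gait-fatigue link). A fast feature-level generator
(`simulate_feature_windows()`) produces modelling-table rows directly for
calibration and power studies where the signal chain is irrelevant; the
coupling strength 0.12 used in the power checks was chosen once to give
roughly 80% power for the calibrated (unweighted) test at 60 subjects.

What the generator does *not* emulate: realistic biomechanics (turning,
stairs, shuffling), disease-specific gait signatures, postural transitions,
non-walking movement (cycling, driving), diurnal activity structure, or
gyroscope channels. Passing the validation suite therefore shows that the
pipeline recovers what it is defined to recover under its own signal model
— not that it is clinically validated on any patient population.

## Numerical choices and degenerate inputs

* Butterworth filters are applied forward-backward; contiguous non-missing
  segments are filtered independently and segments shorter than six filter
  lengths pass through unfiltered.
* The CWT kernel is normalised so a unit slope maps to 1; edges use
  reflection padding.
* The alpha parameter is missing when all bout lengths are equal (the MLE
  denominator vanishes) or n < 2; S2 is missing when n < 2; variability
  needs at least 2 valid steps and asymmetry needs both feet in scope.
* Grid-search ties resolve to the first (smallest) parameter combination.
* Constant features make the mixed model unidentifiable; the fit reports
  `converged = FALSE` with missing estimates rather than erroring.

## Problem sizes used in validation

The validation suite exercises the full signal chain on a five-subject,
one-day cohort at 100 Hz (roughly 25 million samples), estimator
consistency at 10^4 draws, mixed-model calibration over 200 simulated
cohorts of 60 subjects x 10 windows, the classification protocol on
feature-level cohorts of 8-24 subjects with 24-30 windows each under the
full printed grids, and the importance rankers over 20 replicates of a
200 x 5 design. These sizes were chosen so each property is measured with
useful statistical resolution (e.g. fold-mean balanced accuracy has a
standard error near 0.02 under the permutation null) while the whole suite
remains runnable on a laptop.
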