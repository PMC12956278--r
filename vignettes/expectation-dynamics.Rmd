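---
title: "Modelling and recovering expectation dynamics in EEG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and recovering expectation dynamics in EEG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppdyn)
```

# The scientific question

During visual statistical learning, a "leading" image category comes to
predict the category of the "trailing" image that follows it. Two
mechanisms have been proposed for how such expectations shape the neural
response to the trailing image. Under *sharpening*, expectation
suppresses neurons not tuned to the expected category, raising the
signal-to-noise ratio of its representation, so multivariate decoding of
the trailing category should be *more* accurate on expected (valid)
trials. Under *dampening*, expectation suppresses the neurons tuned to
the expected category ("explaining away"), so decoding should be *less*
accurate on valid trials. The opposing-process view reconciles the two:
within a trial, an early sharpening stage is followed by a later
dampening stage. A further question is how these modulations evolve
*across* trials while the transitional statistics are being learned.

`oppdyn` implements the full analysis chain needed to ask these
questions of EEG data — trial-sequence design, preprocessing,
time-resolved decoding, cluster-corrected inference, learning-curve and
mixed-model analyses — together with a forward simulator so that every
stage can be validated by parameter recovery on data whose ground truth
is known.

# The experimental design

Nine symbolic scene categories are split into five leading and four
trailing categories. `build_transition_matrix()` assigns roles at
random: four leading categories form the 2:1 condition (each has one
*valid* trailing category, expected with probability 0.75, and one
*invalid* alternative at 0.25; two leading categories converge on each
of the two 2:1 trailing categories), and one leading category is the
1:2 *control*, leading to the remaining two trailing categories with
probability 0.5 each (its trials are labelled *neutral*).

```{r design}
tm <- build_transition_matrix(assignment_seed = 1)
tm$pair_role
```

`generate_session()` expands a per-block allocation into a randomized
session. Proportions are enforced by exact counterbalancing rather than
Bernoulli draws, so the design ratios hold exactly in every session.
The default allocation gives 8 blocks of 216 trials: 44 trials per 2:1
leading category (33 valid + 11 invalid — exactly 75% validity) plus 40
control trials (20 per trailing category), 1728 trials in total. The
published block length (216) is not divisible by five leading
categories, so equal leading-category frequencies are impossible; this
allocation is the smallest-deviation integer solution that preserves
the 3:1 and 50/50 ratios exactly, and it is configurable. Each trial
presents the leading image for 100 ms, an 800 ms interstimulus gap and
the trailing image for 100 ms (trailing onset exactly 0.9 s after
leading onset), followed by a uniform 1.3–2.2 s intertrial interval.
About 5% of trials are flagged as catch trials (inverted trailing
image, response required); they are ordinary trials carrying a flag and
are removed before analysis. Randomization is within block; the trial
order is otherwise unconstrained (immediate repeats of a leading
category are allowed).

```{r session}
sq <- generate_session(tm, design_config(), seed = 1)
summarize_design(sq)
```

# The forward model

`simulate_recording()` synthesizes continuous multichannel EEG from a
trial sequence. Each category has a fixed unit-norm spatial pattern
with occipito-parietal emphasis; each stimulus adds
`base_gain * pattern * template(t)` at its onset. The evoked template
is a smooth biphasic time course (small negativity at ~90 ms, broad
positivity at ~165 ms, negativity of equal magnitude at ~290 ms) so
that both analysis windows — 123–180 ms and 280–296 ms after trailing
onset — carry signal; its Gaussian components keep it band-limited well
below the resampling cutoffs.

Expectation effects are injected as gain modulations of the trailing
pattern: valid trials are scaled by `1 + sharpening_gain(trial)` inside
the early window, invalid trials by `1 + dampening_gain(trial)` inside
the late window. The gain profiles default to the across-trial study
conditions — dampening starts at full strength and decays
logarithmically to zero by mid-session (trial 864 of 1728), sharpening
grows logarithmically from zero over the same range, both with a
60-trial curvature constant — and can be replaced by
`constant_gain()` for stationary within-trial studies. Valid trials
additionally re-embed the leading category's pattern at low gain during
the trailing response, giving memory decoding something real to find.

Noise comprises spatially correlated Gaussian sensor noise, 50 Hz line
noise with per-channel amplitude jitter, and stereotyped blinks
(squared-sine deflections on the vertical EOG, attenuated copies on
frontal channels, Poisson onsets). The simulator does not model 1/f
background spectra, alpha rhythms, channel drift or muscle artifacts;
passing tests on synthetic data therefore validates the *pipeline
logic* (filters, decompositions, cross-validation, inference), not the
pipeline's robustness to every artifact class in real recordings.

# Preprocessing

`preprocess_pipeline()` runs the canonical order: high-pass (0.1 Hz)
and notch (48–52 Hz) filtering, downsampling (default 300 Hz), blink
removal, average re-referencing with denoising source separation,
epoching from −200 ms to 2600 ms around the leading onset, baseline
correction (−200–0 ms), and RMS-based epoch rejection.

Numerical choices worth knowing:

* **Filtering.** A fifth-order Butterworth high-pass at 0.1 Hz has
  poles essentially on the unit circle at EEG sampling rates;
  forward–backward filtering in transfer-function form diverges. The
  package instead applies the zero-phase (forward–backward, i.e.
  squared-magnitude) Butterworth response in the frequency domain, with
  30 s of mirror padding that is continuous at every boundary. This is
  exact zero-phase filtering and stable at any rate; the notch response
  is zero at the band centre, so 50 Hz attenuation far exceeds 40 dB.
* **Resampling** is done by Fourier truncation (ideal anti-aliasing for
  band-limited signals); event samples are remapped by rounding, so
  stimulus-locked times carry at most half a sample of jitter. When the
  rate ratio allows, filtering and resampling are fused into a single
  FFT round trip; the two paths agree away from the padded boundaries.
* **Blink removal.** Onsets are detected on the bipolar vertical EOG as
  robust z-score (>4) threshold crossings with a 300 ms refractory
  period — the detection rule is a package choice, exposed in the
  configuration. Segments from −200 to +400 ms around each onset are
  concatenated, decomposed by SVD, and the top two spatial components
  are projected out of those segments only.
* **DSS.** Epochs are average-re-referenced, whitened on the total
  single-trial covariance, and the covariance of the trial-averaged
  data is eigen-decomposed in whitened space; sensor data are
  reconstructed from the `n_keep` most reproducible components
  (default 10 for 64 channels). DSS targets the phase-locked evoked
  response, which is category-*agnostic*: the grand average contains
  the mean of the category patterns, not their differences, so keeping
  too few components can attenuate exactly the directions decoding
  needs. At the reduced study scale (32 channels) the studies keep 12
  of 31 possible components as a balance between denoising and
  preserving discriminant directions.
* **Epoch rejection** removes epochs whose RMS (over all channels and
  samples) strictly exceeds the median by 2 SD of the RMS distribution;
  with identical epochs nothing is rejected.
* The 48 Hz low-pass applies only to trial averages (the ERP branch);
  single-trial decoding never sees it.

# Decoding

`run_decoding_suite()` restricts to non-catch 2:1 trials and runs three
analyses split by validity: sensory decoding of the leading category
(leading-locked, 4 classes, chance 0.25), sensory decoding of the
trailing category (trailing-locked, 2 classes, chance 0.5), and memory
decoding of the leading category from trailing-locked data (chance
0.25). A fourth variant (decoding the anticipated trailing category
from leading-locked data) is available behind the `prediction`
analysis name.

Features are principal components of the channel covariance, retained
if their evoked SNR — variance of the trial-averaged projection in the
post-stimulus window over its variance in the baseline window — is at
least 8 dB, in descending SNR order. Selection is fitted within
training folds by default (`selection = "per_fold"`); the `"global"`
option reproduces selection-before-decoding workflows. Note that this
selection criterion is label-free, so the leakage it can introduce is
benign for class separation; the per-fold default is simply the
conservative choice.

Cross-validation follows the leave-one-per-cell scheme: each test set
holds exactly one randomly chosen trial from every observed
leading-by-trailing cell — eight cells when both validities are pooled,
four within a validity subset, since a validity subset realises only
its own leading-trailing pairings. The number of folds is the minimum
per-cell count, optionally capped (`max_folds`); surplus trials beyond
the folds appear in training sets only (or are discarded, via
`surplus`). The classifier is a linear SVM with `C = 1` on features
standardized with training-fold statistics; multi-class problems use
one-vs-one voting with ties broken by summed decision values.

# Statistics

All time-resolved tests are corrected over time by cluster-mass
permutation: contiguous runs exceeding the two-tailed forming threshold
(`alpha = 0.05`) are scored by the sum of their statistic, and each
observed cluster is referred to the permutation distribution of the
maximum cluster mass (sign flips of subject effects for one-sample and
paired tests, condition-label shuffles for the trial-level ERP
contrast), giving `p_fwe = (1 + #{null >= mass}) / (n_perm + 1)`. The
nonparametric correction replaces parametric random-field approaches:
it is exact under exchangeability, makes no smoothness assumptions that
synthetic data could not satisfy, and uses the same forming threshold
(0.05) and cluster-level criterion (p < 0.05). The ERP contrast is
trial-level (fixed effects) to mirror a contrast with thousands of
degrees of freedom; the exploratory whole-sensor variant corrects over
channels and time with a max-statistic null across channels.

# Learning dynamics

`trialwise_benefit()` turns per-trial correctness, averaged over a
within-trial window, into an across-trial benefit series: each validity
series is smoothed with a centred 21-trial moving average (a 0/1
correctness series needs smoothing before it can be read as an accuracy
time course), the two series are aligned on the session trial index by
interpolation, and the difference is resampled onto a fixed 200-point
grid spanning the session — the fixed grid makes subjects comparable
regardless of how many of their trials were tested and rejected.

`fit_log_stabilization()` fits `benefit(t) = a + b log(t)` by least
squares and reports the *stabilization index*: the first trial at which
the fitted curve changes by less than 0.1% per trial, computed on the
fitted curve (relative to `|fit(t)|`, or the absolute change where the
fit crosses zero). `bin_decoding()` averages window-level correctness
within four consecutive equal-count trial bins, and
`fit_validity_bin_lme()` models the first two bins (the learning phase)
as `accuracy ~ validity * bin + (1 | subject)` with Satterthwaite
degrees of freedom, removal of rows whose Cook's distance exceeds the
mean by 3 SD (one refit, no iteration), Cohen's *f* from the marginal
fixed-effects R², and Holm–Bonferroni-adjusted post hoc paired
contrasts (validity within bins, bins within validity). A singular
random-intercept fit falls back to a fixed-effects model with a
warning.

# Behaviour

`analyze_rts()` mirrors the categorisation-task analysis: reaction
times beyond 2 SD of the pooled raw mean are excluded (a single global
threshold; per-condition thresholds can be emulated by calling the
function per condition), the remainder are log-transformed and averaged
per subject and condition, empty cells are imputed with the
across-subject condition mean, and a repeated-measures ANOVA plus the
three paired contrasts with Cohen's d are reported.
`brain_behaviour_correlation()` gives Pearson correlations between
per-subject RT effects and decoding effects per window.

# Validation studies and their problem sizes

The package validates itself by parameter recovery at a reduced scale
chosen so the full suite runs on a single core: 32 channels, 256 Hz
acquisition downsampled to 128 Hz, one 240-trial block at the full
design ratios (39 valid + 13 invalid per 2:1 leading category, 16 per
control trailing category), decoding over 0.05–0.35 s after trailing
onset with 6 folds per validity. The pipeline itself is scale-agnostic.

* **Effect recovery** (`run_effect_recovery_study()`): 20 cohorts of 12
  subjects with constant gains injected — 2.0 in the early window of
  valid trials, 7.0 in the late window of invalid trials. The gains are
  width-compensated: the late window (16 ms) is ~3.6× narrower than the
  early one (57 ms) and survives resampling as only one or two decoding
  samples, so equal injected effect mass (gain × width) requires the
  gain ratio to match the width ratio. Sensor noise is 4 μV against a
  4 μV evoked peak, placing single-trial decoding in the 0.55–0.85
  range with the unboosted late-window response near the lower end, so
  ceiling compression cannot mask the injected difference. Recovery means the paired cluster test returns an
  early valid > invalid and a late invalid > valid cluster, each at
  cluster-level p < 0.05 and overlapping its injected window.
* **Type-I calibration** (`run_null_calibration()`): 200 null cohorts.
  Because the family-wise error rate of the cluster test is a property
  of the inference given exchangeable inputs, the null cohorts are
  generated at the accuracy-series level (chance plus temporally
  smoothed sampling noise, identically distributed for both
  validities — the structure gain-free decoding produces); the
  end-to-end gain-free null is checked separately on full-pipeline
  simulations in the test suite.
* **Learning-curve recovery** (`run_logfit_recovery()`): noiseless
  `0.1 + 0.05 log(t)` series must be recovered to coefficient error
  below 1e-6 with the stabilization index equal to its analytic value;
  with binomial noise (30 Bernoulli draws per grid point) the median
  index error over 100 replicates stays within 10% of the series
  length.
* **Mixed-model power** (`run_lme_power_study()`): 24 subjects, a pure
  crossover (0.06 accuracy difference in bin 2 only) against 0.03
  between-subject and 0.03 residual SD, detection = Holm-adjusted
  interaction p < 0.05 across the three fixed effects; the same
  machinery with zero effect estimates the false-detection rate.

# Known limitations

* The simulator's noise model is white plus uniform spatial
  correlation; real EEG has 1/f spectra, rhythmic activity and
  non-stationary artifacts that the rejection and denoising stages are
  not stress-tested against here.
* DSS retention and the blink-detection rule are under-determined by
  the published analysis descriptions this design follows; both are
  explicit configuration parameters rather than fixed constants.
* The equivalence between the nonparametric cluster correction used
  here and parametric random-field corrections is conceptual, not
  numerical; cluster p-values from the two frameworks need not match.
* Reading accuracy-benefit series on a 200-point grid and the
  "training-only surplus" fold policy are package decisions where the
  underlying methods allow several constructions; both are
  configurable.
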