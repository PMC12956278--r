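# oppdyn

Dynamics of expectation effects in time-resolved EEG decoding.

## The problem

In visual statistical learning, a *leading* image category
probabilistically predicts the category of the *trailing* image that
follows. Whether expectation **sharpens** the neural representation of
the expected category (raising its decodability) or **dampens** it
(lowering its decodability) — and whether both happen at different
post-stimulus latencies, and at different stages of learning — is a
live question in cognitive neuroscience. Answering it requires a fairly
long analysis chain, every link of which can silently bias the result:
trial-sequence design with exact transition statistics, artifact
removal, time-resolved multivariate decoding with leakage-safe
cross-validation, family-wise-error-corrected inference over time, and
across-trial learning-curve models.

`oppdyn` implements that chain for R, together with a forward EEG
simulator, so that the whole pipeline can be validated end to end by
parameter recovery: inject known sharpening/dampening modulations into
synthetic EEG, run the full analysis, and check that they are recovered
in the right windows with the right signs — and that nothing is
"recovered" when nothing was injected.

For whom: researchers analysing paired-image statistical-learning EEG
experiments, and anyone needing a tested reference implementation of
time-resolved decoding with SNR-based PCA selection,
leave-one-per-design-cell cross-validation, cluster-mass permutation
FWE correction, logarithmic learning-curve stabilization analysis, or
validity-by-bin mixed models.

## The model in brief

* **Design**: 5 leading and 4 trailing categories. Four leading
  categories form the 2:1 condition — P(valid trailing | leading) =
  0.75, P(invalid) = 0.25 — and one is a 1:2 control with a 50/50
  split (*neutral* trials). Default sessions have 8 blocks x 216 trials
  = 1728 trials with the ratios enforced exactly by counterbalancing.
* **Decoding**: per time point, a linear SVM (C = 1) on principal
  components whose evoked SNR exceeds 8 dB; cross-validation test sets
  hold one trial per leading-by-trailing cell; valid and invalid trials
  are analysed separately (chance = 0.5 for 2-way trailing decoding,
  0.25 for 4-way leading/memory decoding).
* **Inference**: cluster-mass permutation over time — clusters formed
  at two-tailed p < 0.05, cluster-level p_FWE = (1 + #{max null mass >=
  observed}) / (n_perm + 1).
* **Learning**: the valid-minus-invalid decoding benefit per trial,
  smoothed and resampled to a 200-point grid, is fit by
  `benefit(t) = a + b·log t`; the *stabilization index* is the first
  trial where the fitted curve changes by < 0.1% per trial. Binned
  accuracies (4 bins, bins 1–2 analysed) enter
  `accuracy ~ validity * bin + (1 | subject)` with Cook's-distance
  outlier removal and Holm–Bonferroni post hocs.

## Worked example

```r
library(oppdyn)

# design: transition matrix and a default 1728-trial session
tm <- build_transition_matrix(assignment_seed = 1)
sq <- generate_session(tm, design_config(), seed = 1)
summarize_design(sq)
#> <design_summary> 1728 trials in 8 block(s) of 216
#>   valid fraction in 2:1 condition: 0.7500
#>   control trailing split: 0.5 / 0.5
#>   catch fraction: 0.0498

# one simulated subject, end to end, at the reduced study scale
# (32 channels, 256 Hz, 240 trials), with strong injected effects
res <- simulate_study_subject(seed = 42, sharpening_gain = 2,
                              dampening_gain = 7)
res$valid
#> <decoding_result> sensory_trailing (valid), 39 time points, chance 0.50, mean accuracy 0.585

# group inference over a cohort of such subjects
# (see run_effect_recovery_study() for the packaged study)
```

`summarize_design()` prints the exact design arithmetic: 1728 trials in
8 blocks of 216, exactly 75% valid trials within the 2:1 condition, an
exact 50/50 trailing split in the control condition, and ~5% catch
trials. `res$valid$accuracy` / `res$invalid$accuracy` are the
time-resolved decoding accuracies whose paired contrast shows the
injected early valid > invalid (sharpening) and late invalid > valid
(dampening) effects.

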