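# gazedx

Gaze-based classification of neurodevelopmental disorders from
facial-emotion-identification trials.

## The problem

During facial-emotion recognition tasks, adults and children with autism
spectrum disorder (ASD) and adults with schizophrenia (Sz) scan faces
differently from controls: eye-region fixation is reduced (most strongly
in Sz), mouth fixation is elevated in ASD, and scan paths are longer and
more dispersed in both clinical groups — with the size of these contrasts
depending on the *emotion being shown*. `gazedx` is an analysis pipeline
for 120 Hz binocular eye-tracking of 5-second emotion-identification
trials (21 stimuli / 7 emotions for adults, 32 / 4 for children) that
turns raw gaze streams into a participant-level diagnostic prediction and,
along the way, into interpretable group statistics. It is aimed at
computational-psychiatry researchers who want a tested, reproducible
implementation of this design.

## The method

1. **Event detection (I-VT).** The cyclopean gaze point (mean of the valid
   eyes) is labelled per sample by velocity-threshold identification:
   angular velocity between consecutive valid samples (bridging gaps up to
   75 ms) above 100°/s ⇒ saccade, otherwise fixation. Trial features:
   fixation-sample counts inside per-stimulus eyes/nose/mouth AOIs, the
   saccade count, and the scan-path length

   *L* = Σ‖pᵢ₊₁ − pᵢ‖ / #pairs over consecutive valid sample pairs,

   in normalized screen units. Trials with *L* = 0 or < 40% valid samples
   are excluded.
2. **Group statistics.** Per emotion and feature, trial-pooled group means
   ± SD with Welch's *t*-tests (disorder vs. control) and
   Benjamini–Hochberg correction.
3. **Per-trial classifiers.** A 3-feature MLP (three hidden layers of 5)
   and a small CNN (3×3 conv ×8 → pool → 3×3 conv ×16 → pool → 2 logits)
   on a 2-channel 34×34 input: the stimulus and a gaze heat map (visited
   pixels set to 1, Gaussian-blurred with σ = 10 px, face-centred crop,
   area-downsampled). Adam, cross-entropy, ≤300 epochs, early stopping
   (patience 15) on a participant-level 8:2 validation split, learning
   rate chosen by nested leave-one-participant-out (LOPO) selection.
4. **Aggregation — the core idea.** A participant's 21 (or 32) binary
   trial predictions, ordered by stimulus, are combined either by majority
   (hard) voting or by a random forest that learns *which stimuli are
   diagnostic* and weights them accordingly; averaged per-face Gini
   importances expose the informative emotions.
5. **Evaluation.** Nested LOPO with strict fold isolation, confusion
   metrics (Accuracy = (TP+TN)/N, Sensitivity = TP/(TP+FN),
   Specificity = TN/(TN+FP); disorder = positive), and an exact binomial
   test against chance.

Because the clinical recordings such a design targets are generally not
shareable, the package includes a calibrated synthetic cohort generator
(`simulate_cohort()`) whose defaults encode the published group × emotion
structure, plus schematic face stimuli with per-stimulus AOIs. The methods
vignette (`vignettes/gazedx-methods.Rmd`) documents the generative model,
the calibration choices and their limits.

## Worked example

```r
library(gazedx)

profiles <- default_profiles("adult")
cfg <- cohort_config(list(list(profile = profiles$control, n = 6),
                          list(profile = profiles$Sz, n = 6)),
                     population = "adult", seed = 42)
cohort <- simulate_cohort(cfg)

features <- cohort_features(cohort)           # I-VT events -> trial features
tab <- emotion_feature_table(features)        # Welch + BH group statistics
subset(tab$summary, emotion == "surprise" & feature == "fix_eyes")
#>    emotion  feature   group n_trials     mean        sd         label
#> 5 surprise fix_eyes control       18 252.5556 129.65711 252.56±129.66
#> 6 surprise fix_eyes      Sz       18 161.1667  61.87773  161.17±61.88

res <- nested_lopo(cohort, "baseline",
                   cfg = train_config(max_epochs = 60, early_stop_patience = 10,
                                      lr_grid = 1e-2, seed = 1),
                   features = features)
metrics_report(res, "forest")[c("accuracy", "sensitivity", "specificity",
                                "binomial_p")]
#> accuracy 1.000  sensitivity 1.000  specificity 1.000  binomial_p 0.0005
head(average_importances(res$forests, "adult")[
  order(-average_importances(res$forests, "adult")$mean_importance), ], 3)
#>    face  emotion mean_importance
#> 1     1 surprise      0.05491136
#> 13   13    anger      0.05401121
#> 20   20     fear      0.05366326
```

Reading the output: control participants keep ~253 of 600 fixation samples
on the eyes during surprise trials versus ~161 for the Sz profile, the
LOPO classification of this (easy, homogeneous) synthetic contrast is
perfect with p ≈ 5·10⁻⁴ against chance, and the importance profile is
flat — the simulated Sz contrast here is present in *every* emotion, so no
stimulus dominates. Synthetic groups are homogeneous, so such accuracies
are optimistic relative to clinical cohorts; see the vignette.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/gazedx.R simulate --population adult --seed 7 --out cohort/
Rscript inst/cli/gazedx.R features --cohort cohort/ --out features.csv
Rscript inst/cli/gazedx.R stats    --features features.csv --out stats/
Rscript inst/cli/gazedx.R evaluate --cohort cohort/ --variant baseline --out report/
```

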