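---
title: "Gaze-based classification of neurodevelopmental disorders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedx)
```

## The problem

Adults and children with autism spectrum disorder (ASD) and adults with
schizophrenia (Sz) scan faces differently from controls while identifying
facial emotions: eye-region fixation is reduced (most strongly in Sz),
mouth fixation is elevated in ASD, and the scan path is longer and more
dispersed in both clinical groups. `gazedx` implements a complete analysis
pipeline for such data: 120 Hz binocular gaze recordings of 5-second
emotion-identification trials (21 stimuli across 7 emotions for adults,
32 across 4 for children) are reduced to interpretable eye-movement
features, turned into per-trial diagnostic predictions, and aggregated
into one participant-level label, with the aggregation step — a random
forest over the ordered per-stimulus predictions — learning *which
stimuli* (hence which emotions) carry diagnostic signal.

Because the clinical recordings this design targets are not publicly
available, the package ships a generative simulator (`simulate_cohort()`)
whose defaults encode the published group-level structure. Every stage is
therefore testable end to end, with the important caveats spelled out
below.

## Event detection and trial features

Gaze samples carry two eyes and per-eye validity. `cyclopean_points()`
averages the eyes when both are valid and falls back to the valid eye
otherwise. `classify_events_ivt()` implements velocity-threshold
identification (I-VT): the visual angle between consecutive valid samples
(bridging invalid gaps up to 75 ms) divided by the time step, with samples
*strictly above* 100 deg/s labelled saccades and all others fixations. The
first valid sample of a run inherits its successor's label. No minimum
fixation duration or fixation merging is applied, and velocities use plain
two-sample differencing: these are the minimal, canonical choices for I-VT,
and nothing downstream consumes event durations.

Angular velocity needs physical geometry. The display is modelled as a
24-inch 16:9 panel (531 x 299 mm) viewed from 650 mm; this is configurable
(`display_geometry()`) and velocities scale with it.

Three features summarize a trial: per-AOI *fixation-sample counts* (the
number of fixation-labelled samples inside the eyes/nose/mouth polygons,
boundary inclusive — on a 600-sample trial these are counts out of 600,
which is the scale on which group means around 140–300 are meaningful),
the *saccade count* (maximal runs of saccade samples), and the *scan-path
length*: the mean Euclidean displacement per consecutive valid sample
pair, in normalized screen units, with invalid samples breaking the chain.
Trials are excluded when the scan path is exactly zero (gaze never moved —
tracking failure or peripheral-vision strategy) or fewer than 40% of
samples are valid.

## The synthetic cohort generator

`simulate_trial()` draws gaze as a two-state process: fixation epochs of
isotropic Gaussian jitter (SD `fixation_jitter_sd`, truncated to the
display) around an anchor inside an AOI, interleaved with saccadic
relocations occurring independently per sample pair at rate
`saccades_per_second`. A relocation samples its destination AOI from the
profile's per-emotion dwell distribution; same-AOI relocations are
ballistic steps of Rayleigh-distributed length (mean `saccade_amplitude`)
reflected into the AOI rectangle, cross-AOI relocations land uniformly in
the destination. Samples lose both eyes independently at
`invalid_sample_rate` (the pipeline's validity filter only thresholds the
valid fraction, so no burst model is needed) and occasionally one eye.

`default_profiles()` calibrates dwell fractions so the *expected* eye- and
mouth-AOI fixation-sample counts match the published group-by-emotion
means, and scales jitter per emotion so scan-path contrasts follow the
published pattern, giving the adult orderings eyes: control > ASD > Sz and
scan path: Sz > ASD > control in every emotion. Child profiles, built the
same way from the child tables, carry much smaller contrasts concentrated
in anger-trial eye dwell.

One deliberate deviation: the published scan-path magnitudes (0.05–0.22
normalized units per sample pair) are not jointly attainable with the
published fixation-sample counts under a 100 deg/s I-VT threshold at
120 Hz — 0.05 screen units per 8.3 ms is roughly 260 deg/s, so any
process with that average step would have nearly every sample labelled a
saccade. The generator therefore reproduces the *orderings* and relative
per-emotion pattern of the scan path at physically consistent magnitudes
(about 0.005–0.015), while matching the fixation-count means on their
published scale. `expected_trial_features()` exposes the profile-implied
expectations (closed-form for counts and validity; the mean saccadic jump
length is estimated from the seeded anchor-relocation chain alone), and
the test suite checks that simulated cell means recover them.

What the generator does *not* emulate: participant-level random effects
(every participant of a group shares one process; real cohorts are
heterogeneous and the real participant-classification problem is
correspondingly harder), temporal structure of validity loss (blinks come
in bursts), smooth pursuit, microsaccade dynamics, and any dependence of
gaze on the identity of the photographed face beyond its AOI layout.
Passing pipeline tests on synthetic cohorts demonstrates that the
machinery is correct and calibrated, not that comparable accuracy would be
obtained on clinical data.

## Heat maps and model inputs

For the image-based classifier, each trial becomes a two-channel 34 x 34
input: the schematic grayscale stimulus and a gaze-retention heat map.
The heat map sets every visited pixel to 1 at the native 1920 x 1080
resolution (idempotent across repeated visits), blurs with a normalized
discrete Gaussian (sigma = 10 px, support truncated at 5 sigma and
renormalized, reflective boundary — mass is conserved exactly), crops the
largest square centred on the stimulus face box, area-downsamples to
34 x 34 and min-max scales each channel (a constant channel maps to 0).
Blur precedes downsampling because sigma is defined in native pixels. Two
separate channels, rather than an alpha blend, let the classifier relate
gaze locations to facial regions explicitly. The cyclopean point feeds the
heat map, for consistency with event detection.

Since binarize-blur-crop-downsample is linear in the hit map, the pipeline
precomposes the blur Toeplitz, crop selection and area-average operators
per stimulus, evaluating each trial's 34 x 34 heat channel directly from
its hit coordinates. This is exactly equal to the naive full-resolution
path (asserted in the tests to 1e-12) and makes per-trial cost
microseconds rather than ~100 ms.

The stimulus images themselves are schematic faces generated by the
package (head, brows, eyes, nose and an emotion-dependent mouth, with
per-stimulus geometric jitter so AOIs genuinely differ between images of
one emotion); the photographic stimuli of the original task are
copyrighted and are not reproduced.

## Per-trial classifiers and training protocol

The baseline classifier is an MLP with three hidden layers of five units
on the three global features (total fixation samples, saccade count,
scan-path length), z-scored with training-set statistics; the image
classifier is a small CNN (two 3 x 3 convolutions with 8 and 16 filters,
each followed by ReLU and 2 x 2 max pooling, then a 2-logit dense layer —
about 3,000 parameters, deliberately small for ~630-trial training sets).
Both train with Adam on softmax cross-entropy, at most 300 epochs, early
stopping after 15 epochs without validation-loss improvement (best-epoch
weights restored), and a participant-level stratified 8:2
train/validation split. The learning rate is selected by nested
leave-one-participant-out cross-validation over a grid (default 1e-2,
1e-3, 1e-4; ties go to the smallest rate; the inner loop can be capped or
skipped with a one-point grid). Trials inherit their participant's
diagnosis as label, so the per-trial problem is deliberately noisy — the
aggregation stage resolves it.

Two protocol details are this package's own choices, made for statistical
hygiene under leave-one-participant-out (LOPO) evaluation:

* **Class-weighted loss and balanced folds.** LOPO training pools are
  imbalanced in the direction opposite to the held-out class. Because a
  participant's 21 trials are aggregated by vote, even a slight
  class-prior tilt in the trial model is amplified into a systematic
  participant-level bias (with no signal, an unweighted pipeline drifts
  measurably away from chance in either direction depending on the fold's
  composition). The loss therefore weights classes by inverse frequency,
  and `nested_lopo()` subsamples every fold's training pool to an
  identical class-balanced composition (smallest class size minus one per
  class, seeded).
* **Out-of-fold first-stage predictions for the forest** (default
  `forest_mode = "oof_kfold"`). The weighting forest must score a held-out
  participant's *out-of-sample* prediction vector. If its training rows
  are the trial model's predictions on its own training participants,
  the forest calibrates to memorization-inflated prediction rates and
  misjudges out-of-sample vectors when the signal is weak. Inner k-fold
  (default 5) out-of-fold prediction gives the forest training rows with
  the same distribution as the row it must score. The in-sample protocol
  and full inner-LOPO variants remain available (`"insample"`, `"oof"`).

The conv/pool primitives are compiled (Rcpp), the backward pass is
verified against finite differences in the test suite, and training is
bit-reproducible under a fixed seed.

## Aggregation: hard voting vs. stimulus weighting

`hard_vote()` is majority rule over a participant's trial predictions
(ties — only possible for the even-length child set — go to the disorder
class, a documented convention). The weighted alternative fits a random
forest (500 trees, Gini impurity, unlimited depth, seeded, balanced
stratified bootstrap) on the participants x faces matrix of binary
predictions, ordered by face number — not presentation order, which is
randomized per participant, so importance is attributable to the
stimulus. Per-face Gini importances are normalized to sum to one and
averaged across cross-validation folds (`average_importances()`), giving
the per-stimulus informativeness profile. When the diagnostic signal is
confined to a subset of emotions, the forest concentrates importance on
exactly those faces and outperforms hard voting, which dilutes the
informative trials among the uninformative majority — this is the central
mechanism the package exists to test, and it is exercised as a simulation
property in the acceptance suite.

## Evaluation

`nested_lopo()` leaves one participant out per fold; scaling, learning
rate, trial model and forest are fitted strictly inside the fold (the
result object carries a per-fold audit trail of training participants).
Folds whose training pool loses a class are recorded as failures and
counted as errors so totals always reconcile. Metrics follow the standard
confusion formulas with disorder as the positive class; the exact binomial
test against chance doubles the smaller tail (capped at 1), with the
chance rate configurable (0.5 by default; the majority-class rate is the
common alternative — the choice is reported alongside results because the
two conventions differ for 16/15 cohorts).

Group statistics (`emotion_feature_table()`) pool *trials*, not
participants, matching the per-emotion trial counts convention of the
study design: per emotion and feature, group means ± SD and pairwise
Welch's t-tests of each disorder group against controls, with
Benjamini-Hochberg correction applied within each feature across all
emotion x pair tests. The correction family is a design choice (the
natural alternatives are per-emotion or global families); it is recorded
in the output so results are auditable.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at the
study's own design sizes (16 + 15 adult participants, 21 trials each,
600 samples per trial) with reduced training schedules (tens of epochs
for the MLP, a few epochs for the CNN, one-point learning-rate grids) and
10-seed replications for the simulation properties; these sizes were
chosen so a desk-scale machine reproduces everything in minutes while the
statistical checks retain power. Degenerate inputs are handled
deterministically: boundary gaze points count as inside an AOI, a
zero-variance feature z-scores to 0, a forest with all-constant features
falls back to the majority class, and empty validation pools validate on
the training set.

## Known limitations

* Synthetic cohorts lack participant heterogeneity, so LOPO accuracies on
  signal cohorts are optimistic relative to clinical data; the package's
  claims are about machinery, calibration and the weighting mechanism.
* The published scan-path scale is intentionally not reproduced (see
  above); comparisons against it should use orderings, not magnitudes.
* The binomial band checks treat fold outcomes as independent; vote-based
  LOPO predictions within one cohort are positively correlated, so those
  bands are approximate and occasional boundary excursions under
  resimulation are expected.
* Whether the original analysis counted fixation *events* or fixation
  *samples* is ambiguous; sample counts are implemented because the
  published magnitudes (hundreds per 5-second trial) are only consistent
  with 120 Hz sample counts.
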