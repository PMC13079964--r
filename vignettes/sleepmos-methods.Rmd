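---
title: "Methods: hybrid LSTM + metaheuristic-optimised SVM sleep-quality modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid LSTM + metaheuristic-optimised SVM sleep-quality modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sleepmos` predicts two objective sleep-health targets from epoch-level
wrist actigraphy (one activity count per minute plus an off-wrist flag):
a weekly sleep-quality score with three classes, and a sleep-consistency
score with four classes. This vignette is the package's own account of the
model, the choices that were genuinely open, and what the synthetic-data
experiments do and do not demonstrate.

## The pipeline

A fit with `sleepmos()` runs six stages in a fixed order:

1. **Preprocessing.** Leading and trailing off-wrist runs are trimmed;
   interior gaps are forward-filled; one-minute counts are downsampled to
   hourly means; the hourly series is cut into overlapping 24-hour windows
   stepped by 12 hours; all values are min-max scaled to [0, 1].
2. **Labelling.** Per-night sleep parameters are derived by Cole-Kripke
   style epoch scoring plus rest-interval detection, then mapped to the two
   composite scores (below). On synthetic cohorts, noiseless ground-truth
   labels are available instead.
3. **Deep features.** A stacked LSTM (75-50-25-15 units for the weekly
   target, 100-80-60-40 for consistency; tanh cells; dropout 0.2; input
   24 x 1) is trained end-to-end with a temporary softmax head on the
   window labels; the final layer's last-time-step hidden state (15 or 40
   values) is the deep feature vector.
4. **Statistical features.** Mean, population-SD and zero-percent of each
   normalised window.
5. **Feature selection.** Two wrapper searches over the deep block - a
   binary genetic algorithm (crossover 0.6, mutation 0.033, population 20,
   20 generations, linear-SVM fitness) and a geometric, velocity-free
   binary PSO (per-bit recombination from current/personal-best/global-best
   positions with probabilities 0.33/0.34/0.33, per-bit mutation 1/n,
   population 20, 20 iterations, logistic-regression fitness) - combined by
   set union. Statistical features bypass selection and are always
   appended.
6. **Classification and reporting.** A linear SVM with `C = 0.1`
   (one-vs-rest for more than two classes) on the fused selected features,
   evaluated by stratified 10-fold cross-validation grouped by participant,
   with permutation feature importance computed on the held-out folds.

## The two composite scores

**Weekly quality (0-12, lower is better).** Four nightly components -
efficiency (percent of time in bed spent asleep), sleep-onset latency,
wake after sleep onset (WASO), and duration - are averaged over the week.
Because the raw components have incommensurate units, each average is
mapped to a PSQI-style 0-3 subscore before summation; this is the only
reading under which a 0-12 range is attainable from four components. The
bands are: efficiency >= 85 / 75-84 / 65-74 / < 65; latency <= 15 / 16-30 /
31-60 / > 60 min; WASO <= 20 / 21-40 / 41-60 / > 60 min; duration >= 420 /
360-419 / 300-359 / < 300 min. Efficiency, latency and duration bands are
the standard PSQI conventions; PSQI has no WASO band, so the WASO bands
are a package choice mirroring common actigraphy practice. Classes: score
< 5 Good, 5-8 Average, > 8 Poor.

**Consistency (lower is better).** A weighted sum of three regularity
components, `0.4 * SleepVar + 0.3 * WeekendDiff + 0.3 * MidpointVar`.
The components' units are not fixed by the published thresholds alone; the
package implements SleepVar and MidpointVar as standard deviations in
minutes (duration SD; circular SD of the sleep midpoint on the 24-hour
wheel) and WeekendDiff as the absolute circular difference in minutes
between mean weekday and mean weekend midpoints. True variances and a
duration-based WeekendDiff are selectable via the configuration. The SD
reading is the only one under which the printed class thresholds (50, 200,
400) correspond to human-scale variability: an SD of 50 minutes of nightly
duration is a noticeably irregular sleeper, while a variance of 50 min^2
(SD ~7 min) would label nearly everyone irregular. Classes: < 50 Good,
[50, 200) Average, [200, 400) Poor, >= 400 Very Poor; boundary values
fall in the upper class.

## Epoch scoring and rest-interval detection

The source framework leaves the per-epoch sleep/wake rule unspecified
beyond citing the Cole-Kripke tradition, so the package implements the
classic one-minute variant: a weighted sum over a seven-epoch window
(weights 0.106, 0.054, 0.058, 0.076, 0.230, 0.074, 0.067 for offsets -4
to +2) scored sleep when below 1.0. The threshold and weights are
configurable, and Webster rescoring is available but off by default.
Because no diary or event-marker channel exists, the in-bed (rest)
interval of each night is detected as the longest sustained run of
quiescent epochs between 18:00 and the following noon, where quiescence is
a centred 11-minute moving average below 10% of the record's high-activity
level (minimum threshold 5 counts). Latency is the time from rest start to
the first run of five consecutive sleep epochs ("persistent sleep", the
usual actigraphy convention); WASO counts wake strictly between onset and
the last sleep epoch; efficiency is duration over time in bed; midpoints
are handled circularly so sleep spanning midnight is not torn apart.

## The LSTM extractor

No deep-learning runtime is part of the package's dependency set; the
stacked LSTM is implemented in vectorised base R (forward pass,
backpropagation through time, Adam). The analytic gradients are verified
against central-difference numerical gradients in the test suite to
1e-7. Training details that the source framework leaves open were fixed
once: cross-entropy loss through a temporary softmax head on the window
labels; Adam with learning rate 1e-3; batch size 32; up to 100 epochs
with early stopping (patience 10) on a 10% stratified validation split;
inverted dropout masks between layers, disabled at inference so feature
extraction is deterministic. Features come from the last time step of the
final layer rather than a pooled sequence; the head is retained only for
the pure-LSTM baseline variant.

## Feature selection

Both searches operate on the deep block only; the three statistical
features are always appended afterwards. The genetic algorithm uses
tournament selection of size 2, single-point crossover, per-bit flip
mutation and elitism of one - the classic attribute-selection operator
set matching the published hyperparameter table. The PSO variant is the
geometric, velocity-free form: the velocity-update equation appears in
the source only as motivation, and its prose describes a velocity-free
recombination, which is what is implemented. Fitness is 5-fold stratified
CV accuracy of the wrapper classifier (10-fold CV is reserved for final
evaluation); fitness evaluations are memoised per mask within a run, ties
break towards smaller subsets (parsimony), and the best-ever subset is
tracked so reported fitness never decreases across generations. The empty
mask scores 0 rather than erroring. `report_frequency` in the
configuration is interpreted as log-every-N-evaluations.

## Evaluation protocol

Cross-validation is grouped by participant: all windows of one recording
stay in one fold, because window-level splits would let the classifier
recognise participants rather than sleep quality. Folds are reduced (with
a warning) when a class has fewer participants than folds. Multi-class
AUC is one-vs-rest from decision scores, macro-averaged. Participant-level
predictions are majority votes over a participant's windows with ties
resolved to the worst class (conservative). The ablation variants toggle
exactly one component each; the tree baselines (random forest, gradient
boosting, 100 trees/rounds) consume the same fused feature matrix. An
80:20 grouped holdout exists alongside CV (the source describes both
without reconciling them; CV is primary here). The LSTM extractor is
trained once on the pooled windows before classifier-level CV - a mild
optimism shared by all SVM-family variants equally; the pure-LSTM variant
retrains per fold since its classifier is the network itself.

## The synthetic cohort generator

The generator emulates the data regime the pipeline expects: 7 days of
one-minute counts starting at noon, a diurnal rhythm (negative-binomial
counts, day mean 250/min), per-night sleep windows with controllable
latency, WASO (realised as discrete awakening bouts so fragmentation is
visible to zero-percent and SD features), duration, efficiency (via
terminal wake), night-to-night variability, and a weekend bed-time shift
driving the weekday/weekend contrast. Per-participant seeds are derived
as cohort seed + index; all randomness is locally seeded.

Calibration choices, made once at design time: nocturnal counts are
mostly zero (class-dependent mean 0-1.2/min for the weekly-quality
profiles - good sleepers lie still, poor sleepers are restless - which
also gives the zero-percent feature its intended signal); diurnal levels
carry a mild fatigue gradient (280/240/190 counts/min for
Good/Average/Poor), as chronically poor sleepers are less active by day;
awake-in-bed epochs average ~3 counts/min, high enough to score wake
under the Cole-Kripke weights yet quiescent for rest-interval detection.
The default weekly cohort is 28 participants (10/10/8 in classes
Good/Average/Poor); the consistency cohort is 40 (10 per class).

One honest limitation: under the SD-in-minutes reading of the consistency
score, the Very Poor band (>= 400) sits at the ceiling of what seven
nights can produce - the weekend term is circularly capped at 720 min and
duration SD at the plausibility clamp - so the shipped class-3 profile
(near-bimodal durations, 12-hour weekend shift) reaches its band for
roughly 70% of participants while classes 0-2 reach 90-100%, keeping the
cohort-level agreement above 90%. Extreme consistency profiles also sleep
through the day, outside the 18:00-noon rest-detection window, so
scoring-derived consistency labels are only meaningful for moderate
profiles; classification experiments therefore use the generator's
ground-truth labels.

What passing on synthetic data shows - and does not. The cohorts exercise
every code path under known ground truth: parameter recovery, class
realizability, selection behaviour, ablation directions. They do not
contain device-specific count artefacts, napping, shift work, or
population heterogeneity, so accuracy figures on synthetic cohorts
characterise the pipeline, not expected performance on any clinical
cohort.

## Problem sizes used in the shipped experiments

The acceptance experiments run at the study shapes where those are
stated: the 28-participant weekly cohort for the end-to-end fit, the
400-window / 15-feature / 3-informative planted design with 20 seeded
runs for selection recovery, 50 shuffled-label repetitions for null
calibration. Experiments that repeat the entire pipeline many times use
deliberately compact instances chosen as the package's own
operating point for repeated simulation: the ablation-direction study
uses 20 cohorts of 15 participants x 4 days with a 30-epoch extractor
and 12 x 10 search budgets, and the exhaustive-search equivalence check
uses 8-feature spaces (255 subsets) on 150 rows. These sizes are stated
here so the experiments are reproducible as designed.

## Numerical conventions and degenerate inputs

Min-max normalisation maps constant input to all zeros. Records entirely
off-wrist, empty cohorts, single-class training labels, empty feature
masks (fitness 0), C <= 0, dropout outside [0, 1) and mismatched mask
spaces raise typed errors naming the violated constraint. A rest interval
without persistent sleep yields duration 0, efficiency 0 and latency
equal to the interval length rather than an error. Importance values may
be negative and do not sum to any total. Seed fan-out from a single
master seed (`seed` argument of `sleepmos()` / `run_pipeline()`) derives
per-stage seeds by fixed offsets, so one integer reproduces a whole run.
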