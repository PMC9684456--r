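---
title: "Weak supervision, label cleaning and uncertainty for AF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak supervision, label cleaning and uncertainty for AF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package studies

Training an atrial-fibrillation (AF) detector for continuous bedside ECG
monitoring runs into two coupled problems. First, expert rhythm labels for
telemetry-scale data are scarce, so one attractive strategy is *weak
supervision*: train a *surrogate* classifier on an external, labelled,
clean diagnostic-ECG cohort and let it annotate the unlabelled target
cohort. The resulting labels are "weak" — nobody verifies them — and they
inherit both the surrogate's errors and the domain gap between clean
diagnostic recordings and noisy telemetry. Second, a deployed detector
should know when not to be trusted: predictions on artifact-laden or
out-of-distribution (OOD) inputs should come with a usable uncertainty
signal, and predicted probabilities should be calibrated.

`afuq` implements that full study loop as a reusable, tested pipeline:

1. a **synthetic ECG cohort generator** that reproduces the statistical
   structure the analysis needs (two rhythm classes, injected noise, an
   abstain-analog OOD class, per-patient indices, controllable label
   corruption), so every stage is testable without any data download;
2. a **dilated 1D convolutional classifier** with two inference modes
   (deterministic; dropout-active sampling);
3. the **training recipe** (Adam, batch 128, learning rate 0.01, weight
   decay 1e-4, up to 200 epochs, early stopping with patience 10 on a
   stratified validation split);
4. **confident learning** label cleaning, applied iteratively during
   training;
5. **uncertainty estimation** by Monte Carlo dropout (epistemic),
   test-time augmentation with 10% random masking (aleatoric), and joint
   sampling of both (combined);
6. an **evaluation** suite (F1/PPV/sensitivity/specificity, Brier, NLL,
   ECE with reliability-curve data, Cohen's kappa, Mann-Whitney U with
   Bonferroni-Holm correction) and ggplot2 figures;
7. a **pipeline** (`run_experiment()`) that wires all of it together.

## The synthetic generator: what it models, and what it does not

Real ICU telemetry is private; the generator emulates only the properties
the method depends on, with a parametric beat-template model rather than a
dynamical heart model.

- **Beats** are sums of Gaussian bumps for the P, Q, R, S and T
  deflections, placed at beat times whose RR intervals are drawn from a
  log-normal distribution with a configurable mean rate and coefficient of
  variation (CV). A log-normal is positive and right-skewed, which is all
  the rhythm statistics require.
- **Sinus rhythm** has low RR CV (default 0.02) and a visible P-wave.
  **AF** has high RR CV (default 0.25), no P-wave, and an irregular 4–9 Hz
  fibrillatory baseline replacing organised atrial activity. These are the
  two discriminating features named in the clinical description of AF, and
  a transparent RR-irregularity baseline (`classify_by_rr_cv()`) verifies
  that the default presets are separable — which is what makes desk-scale
  training testable.
- **Noise** comes in the two annotated categories, high-frequency artifact
  and sub-1 Hz baseline wander, injected on a contiguous random window; a
  segment is flagged `noisy` exactly when the cumulative affected fraction
  reaches 1/4 of the record, mirroring the annotation criterion. Sensor
  drop-off (a flat run) is modelled separately and sets its own flag.
- **OOD segments** emulate recordings annotators abstain on: a paced-like
  morphology (narrow high-slope spike, broadened QRS) buried under severe
  artifact. They carry `y_true = NA`.
- **Leads** are gain-scaled copies of one cardiac source plus independent
  measurement noise. Four leads are an architectural input requirement;
  inter-lead physiology is out of scope.
- **Domain shift** between the external (surrogate-training) domain and
  the target domain is parameter offsets: amplitude scaling, an additive
  broadband noise floor, and a heart-rate distribution shift.

Limits worth stating plainly: the waveforms are not clinically realistic
(no 12-lead morphology, no real noise recordings, no pathological beat
classes beyond the paced-like OOD template), and all realism claims are
restricted to rhythm statistics and morphology presence/absence.

## The classifier and a numerical choice that matters

The network is 13 blocks of 1D convolution (kernel 3, same padding) →
batch normalisation → ReLU → 30% dropout, with per-block dilation rising
from 1 to 8 and dilated max-pooling (window 2, stride 2, dilation equal to
the block's) after blocks 6 and 11, then global average pooling over time
and a single-logit sigmoid head, so variable-length inputs map to one
p(AF). Published descriptions of this family pin the block structure but
not channel widths or the exact dilation schedule; both are configurable
(`network_config()`), with a documented default schedule
1,1,2,2,2,4,4,4,4,8,8,8,8 and a `scale` multiplier for desk-scale runs.

No neural-network library is available in this environment, so the
forward/backward passes and the Adam optimizer are implemented in the
package (C++ kernels via Rcpp; single-precision activations, double
parameters/gradients). Gradient correctness is tested against central
finite differences.

Two implementation details deserve a record:

- **Batch-norm statistics.** With the default learning rate (0.01) the
  weights move fast, and the usual exponential running average of
  batch-norm statistics lags them; through 13 layers that staleness
  compounds into evaluation-mode probabilities shrunk toward the base
  rate even when the model ranks perfectly. The package therefore
  re-estimates the population statistics after every epoch with a
  dropout-free pass over the active training data (precise-BN style
  recalibration). This is a fidelity fix for evaluation-mode inference,
  not a change to the training recipe.
- **Early stopping** monitors binary cross-entropy on a held-out
  stratified validation split (the criterion the text leaves ambiguous),
  and the weights from the best-validation epoch are restored at the end
  of training.

## Confident learning

Cleaning follows the confident-learning construction. The per-class
threshold is the mean predicted probability of that class over the
samples observed-labelled with it,
$t_j = \frac{1}{|N_j|}\sum_{i:\tilde y_i = j} \hat p(\tilde y_i = j\mid x_i)$.
Each sample is assigned a *confident class*: the argmax over classes
whose predicted probability reaches that class's threshold (ties qualify;
an exact probability tie keeps the observed label; samples qualifying for
no class are uncounted). Counting observed label against confident class
gives the 2×2 confident joint; off-diagonal samples are the label-issue
candidates, and the in-training hook (`confident_cleaner()`) prunes
exactly those from the active set every 3 epochs, cumulatively, skipping
(with a warning) any round that would empty a class. Probabilities are
computed dropout-inactive on the current model from the active samples
only; the construction is validated against a brute-force reference on
random instances.

One practical caveat, measured in a pilot and frozen before the
acceptance thresholds were exercised: the quality of the flagged set
depends on how well the probabilities are fitted. Very early in a
from-scratch run, probabilities cluster near the per-class thresholds and
the off-diagonal set is large and unreliable; once the model fits the
data, the flagged set locks onto the corrupted samples. The cleaner
therefore takes a `warmup` argument that holds it idle for the first
epochs of a run (the standard usage of confident learning, where
probabilities come from a trained model), and the desk-scale experiment
and the label-noise-recovery checks use a warmed-up schedule. `warmup = 0`
recovers the plain every-`interval`-epochs schedule.

A second interaction, also diagnosed at desk scale: the early-stopping
monitor is a loss against the *observed* (weak) validation labels, so
when a cleaning round removes a material share of the training data the
model rightly stops fitting the label noise and the monitored loss can
rise for exactly the wrong reason. `train_classifier()` therefore starts
a fresh early-stopping phase (counter and best-weights snapshot) after
every round that prunes at least 1% of the active set, so the returned
weights come from training on the cleaned data.

## Uncertainty estimation

All modes share one summary: a set of T sampled probabilities per
segment, reduced to its mean (used for classification at threshold 0.5)
and its sample standard deviation (the uncertainty estimate).

- `none`: one deterministic pass; std defined as 0 (always confident).
- `epistemic`: T passes with dropout active (Monte Carlo dropout).
- `aleatoric`: T dropout-inactive passes on independently augmented
  views; the augmentation zeroes exactly `round(0.10 × samples)` time
  points, scattered uniformly and shared across leads, preserving input
  length.
- `combined`: joint sampling — each pass draws an independent masked view
  *and* an independent dropout mask — rather than adding two separate
  standard deviations, because a combined estimate is a single number per
  configuration.

T defaults to 30 (configurable); masking scattered single time points
(rather than one contiguous block) is the simplest reading of "random
masking on the input signal" and is documented as a choice. Degenerate
limits are tested exactly: dropout rate 0 gives zero epistemic std, mask
fraction 0 gives zero aleatoric std.

## Evaluation conventions

- **ECE** uses 10 equal-width bins over [0, 1], right-open except the
  last closed bin; `acc(b)` is AF prevalence and `conf(b)` mean p(AF);
  empty bins contribute nothing. The bin table doubles as
  reliability-curve data (`plot_reliability()`).
- **NLL** clamps probabilities to [1e-7, 1 − 1e-7], the same clamp used
  in training.
- **Mann-Whitney U** uses midranks (half-credit ties); the two-tailed
  p-value is exact (null distribution of U) when `n1 * n2 ≤ 400` with no
  ties, otherwise a tie-corrected normal approximation without continuity
  correction. The test itself is standard; these tie and p-value
  conventions are documented and frozen here.
- **Holm correction** is applied within each requested family of group
  comparisons (`compare_uncertainty_groups()`); the family used is always
  explicit in the output.
- **Cohen's kappa** uses marginal-product expected agreement and refuses
  the degenerate case of expected agreement 1.

## The end-to-end experiment and desk-scale choices

`run_experiment()` executes: simulate external/pool/test cohorts → train
the surrogate on the external cohort with a 70/30 stratified split →
curate the pool (drop-off rejection, 1-hour minimum spacing, initial
per-patient cap, boxplot-whisker cap with type-7 quartiles) → weak-label
it with the surrogate (hard label 1 iff p > 0.5; a tie resolves to sinus)
→ train a weak-labels-only model and a confident-learning model → score
all three models under all four uncertainty modes on the labelled test
set → compare uncertainty distributions (clean vs noisy; in-distribution
vs OOD) with Holm-corrected Mann-Whitney tests. Everything derives from
one master seed.

The default `experiment_config()` is deliberately desk-scale: cohorts of
roughly 2000/2400/500 ten-second 4-lead segments at 240 Hz, a
width-reduced network (`scale = 0.25`), and a 20-epoch cap with
early-stopping patience 4. These are
compute-budget choices for a single CPU, stated here so nobody mistakes
them for a full-scale training configuration; the class mix (14% AF among
in-distribution segments), noise rate (27%) and OOD rate (9%) reflect a
realistic ambulatory screening population and are the generator's
defaults, not tuned quantities.

## What this vignette does not claim

No empirical result is asserted here beyond what the package's tests and
`scripts/acceptance.R` compute on synthetic data: metric agreement with
brute-force oracles, label-noise recovery on the separable task,
directional orderings of the model grid (surrogate ECE above the
weak-label-trained models on the shifted test domain; confident-learning
F1 at or above weak-labels-only), and Holm-corrected separation of the
uncertainty distributions for clean vs noisy and ID vs OOD groups.
No empirical numbers beyond those computed by the tests and the
acceptance script are claimed.

## Worked example

```{r}
library(afuq)

# a small end-to-end run (the defaults take a few minutes on one CPU)
cfg <- experiment_config(seed = 1)
exp <- run_experiment(cfg, verbose = TRUE)
tidy(exp)      # 3 models x 4 uncertainty modes
glance(exp)    # one-row summary
exp$comparisons

# figures
autoplot(exp)                                  # reliability curves
plot_uncertainty_density(exp$predictions[["confident_learning.combined"]])
```
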