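---
title: "Methods: decomposing cognition and motor delay in trial-level task data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing cognition and motor delay in trial-level task data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idoct)
```

## The measurement problem

Self-administered digital cognitive tasks record trial-level accuracy and
reaction time (RT). In cohorts where hand-motor impairment co-occurs with
cognitive deficits, both standard summaries are confounded: total-correct
counts absorb mis-taps and timeouts caused by the responding hand, and RTs
absorb motor and device latency. `idoct` implements a decomposition of
trial-level data into condition difficulty, cognitive answer time, a
non-cognitive response delay, and a Cognitive Index, together with the
analyses used to validate that the index is free of the motor confound.

## The decomposition

### Model

Every reaction time is treated as `RT = AT + DT`:

* `AT` (answer time) — the cognitive component. It depends on the trial's
  condition difficulty through a monotone condition-level curve `AT_c`, and it
  scales multiplicatively with a participant's cognitive speed.
* `DT` (response delay time) — a participant-level additive latency from
  motor response, device lag and other non-cognitive processes. It shifts
  every trial of a session by the same amount.

The key identification argument runs through the difficulty gradient: a
*cognitively slower* participant is slower in proportion to how much
cognitive work a trial requires (their RTs scale the condition curve), while
a *motor-impaired or high-latency* participant is slower by a constant
(their RTs shift the curve). A session's delay is therefore estimated as the
intercept of the within-session regression of RT on the frozen condition
curve, floored at zero. The slope of that regression is ridge-shrunk towards
1 with prior weight `n·tau²` (`tau` = 100 ms): in tasks whose answer-time
curve is nearly flat the session carries no slope information, and the
estimate falls back smoothly to the unit-slope mean residual. A plain
mean-residual delay (no slope) was rejected during development because it
assigns *all* person-level slowness — including cognitive slowing — to the
delay, which both contaminates the delay estimate and makes the Cognitive
Index blind to response speed: a participant with uniformly slower answers
would be scored identically to a fast one.

### Calibration on the normative cohort

Per task, on a large normative cohort:

1. **Speed score** `s = clip((P95 − RT)/(P95 − P5), 0, 1)` from the cohort's
   5th/95th RT percentiles; **trial performance** `p = accuracy·(w + (1−w)s)`
   with `w = 0.5`, so a correct but maximally slow response scores `w`.
2. **Raw difficulty** `D_raw(c) = 1 − mean(p)` per condition label.
3. **Ability-scaled difficulty**: difficulty-weighted participant abilities
   `A_i = Σ p·D′ / Σ D′` and `D′(c) = clip(D_raw(c) + (mean A of attempters
   of c − grand mean A), 0, 1)` are alternated until the largest change in
   `D′` falls below `1e-4`. The correction matters when task flows let only
   stronger participants reach harder conditions; without it those
   conditions look too easy.
4. **Answer-time curve**: per-condition means of `RT − DT` are pooled by
   isotonic regression in the order of `D′` (the curve is constrained
   non-decreasing in scaled difficulty), then per-participant delays are
   re-estimated against the curve, and the two are alternated with half-step
   damping until the curve's maximum relative change falls below `1e-4`.
   Two numerical choices are deliberate:
   * *means, not medians*, for the per-condition residual summary: the delay
     intercepts are mean-based, and a median-based curve re-injects a skew
     offset each iteration under right-skewed RTs, so the alternation
     limit-cycles at the millisecond scale and never meets the tolerance.
     Implausible RTs are removed before calibration, which is what the
     median would otherwise have been robust to.
   * *half-step damping*, because the isotonic/clamp composition is not a
     contraction; with damping every task in the default battery converges
     in under 20 iterations.
5. **Anchoring**: the additive split between the curve's level and the
   delays is not identified by the data, so the delay scale is pinned by
   assigning zero delay to the 5th-percentile (fastest) normative
   participants. All delays are therefore *relative to the fastest normative
   responders*, which is the natural zero for a non-negative latency.

The percentiles, the curve, and the normative mean delay
(`dt_reference_mean`) are frozen into the task's difficulty table; patient
sessions are decomposed only against frozen calibrations. Freezing removes
run-to-run coupling and makes the whole estimation path deterministic — no
seed is consumed anywhere in cleaning, calibration or decomposition.

### Session scores

For one participant-session: `DT` as above, per-trial answer times
`AT = RT − DT` (so `RT = AT + DT` holds exactly), and the **Cognitive
Index**

`AS = Σ accuracy · D′(c) · (w + (1−w)·s*) / Σ D′(c)`

where `s*` is the speed score of the answer times against the calibrated
percentiles shifted by the normative mean delay. `AS` lies in [0, 1]; an
all-incorrect session scores exactly 0; among sessions with the same
accuracy pattern, uniformly slower answer times strictly lower the score,
while a purely additive delay leaves it unchanged. Sessions with fewer than
3 usable trials are decomposed but flagged low-confidence. Unknown condition
labels are a hard error — silently imputing a difficulty would corrupt the
weighting.

Trial cleaning removes non-timeout trials outside [200 ms, ∞); 200 ms is the
conventional physiological floor for a deliberate response, and the per-task
response window already bounds the other side. Timed-out trials are kept as
genuine incorrect responses with RT clamped to the window.

## Global factor extraction

Per recovery phase (acute ≤ 14 days, subacute 15–180, chronic > 180 —
bands bracketing the cohort's median assessment days of 4, 94 and 371) and
per metric family (Cognitive Index vs proportion-correct), the participant ×
task matrix is summarised by its first principal axis. Repeat sessions
within a phase are reduced to the one closest to the phase's reference day,
so the factor analysis stays cross-sectional.

The estimator is an expectation-maximisation fit of the probabilistic PCA
model `x = Wz + e` that conditions each row's latent posterior on its
observed entries only, with an automatic-relevance-determination prior on
the loadings (uninformative by default). Missing cells therefore need no
pre-imputation. Initialisation is classical PCA of the mean-imputed matrix —
deterministic, so repeated fits agree without a seed. Iteration stops when
the largest absolute change in `W` is below `1e-4`, the same tolerance used
everywhere in the package. Variance explained is model-based,
`(d_k² + σ²) / (Σ d_j² + p·σ²)`: exact for noiseless low-rank data and
stable under missingness. Loadings are sign-aligned so the mean loading is
positive; phases with fewer than 10 participants are refused rather than
fitted unstably.

## Regression machinery

All confound and interpretability analyses share one covariate model on the
patient cohort:

`outcome ~ age + age² + sex + education + English-second-language +
log(1 + NIHSS) + time-since-stroke (+ impaired hand) +
(1 + time-since-stroke | subject)`

* Continuous covariates are z-scored once, on the analysis table, before any
  model sees them; NIHSS (stroke severity) is `log(1 + x)` and never
  z-scored — its range includes 0 and the log already handles the skew.
  Education is a factor with the lowest level as reference.
* Gaussian outcomes (Cognitive Index, delay time, median RT) are
  Yeo–Johnson transformed (maximum-likelihood λ) and z-scored, so estimates
  are standardized betas; a Shapiro–Wilk residual normality p-value is
  attached to each fit.
* Accuracy is count data and too skewed for any power transform, so correct
  counts out of totals are fitted as an aggregated binomial mixed model with
  a logit link and the same fixed/random structure; estimates are
  standardized log-odds.
* Random-slope fits that are singular (common with ~2 sessions per subject)
  are refitted with a random intercept only and flagged. Wald 95% intervals
  throughout; Satterthwaite p-values for the Gaussian fits, Wald z for the
  binomial.

The hand-impairment analysis fits all four outcomes per task with the
impaired-hand predictor and reports two Benjamini–Hochberg families: within
each task across its four metrics, and across tasks within each metric. The
`confounded` verdict uses the across-task family — the family appropriate to
"in how many of the battery's tasks does impairment reach the metric" —
while the within-task q-values support per-task four-measure displays. Both
are always reported.

Criterion validity regresses the MoCA-like (or IADL-like) score on the
global factor per phase, by ordinary least squares, with uncorrected
p-values: three phase-wise confirmatory regressions are not a screening
family.

## Brain–behaviour association

Canonical correlation analysis links the per-task Cognitive Indices to the
two scalar imaging burden measures (lesion volume, white-matter
hyperintensity volume), per phase from the subacute stage on (concurrent
imaging starts there). The fit is the SVD-whitening closed form; with 18
cognitive and 2 imaging variables there are exactly 2 modes. The Cognitive
Index matrix is completed with the phase's EM-PCA posterior means before the
CCA, so listwise deletion only removes participants without imaging —
otherwise scattered task-level missingness would discard about half the
rows. Inference is by permutation of the imaging rows (default 9999
permutations, seeded): each mode's canonical correlation is re-estimated per
permutation and `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`. Back-projected
loadings (correlations of each original variable with its own block's
variates) are the interpretable output; weights are not interpretable under
collinearity. Sign convention per block and mode: the largest-|loading|
variable loads positively.

## The synthetic cohort generator

No suitable trial-level stroke dataset is openly available, so validation
runs on a simulator whose defaults define the packaged benchmark: 400
normative participants and 200 longitudinal patients across an 18-task
battery (~40 trials per task, 5 graded conditions each). Demographics,
stroke severity, impaired-hand prevalence (47/171), phase timing and
follow-up rates are anchored to the published characteristics of a large
normative cohort (N = 6364, age 60.8 ± 10.1) and a longitudinal stroke
cohort (N = 171, age 63.01 ± 14.1, NIHSS 4.93 ± 4.66 in 0–26). NIHSS is
drawn as a rounded gamma with that mean and SD — non-negative and
right-skewed, as severity scores are; a 0-truncated normal would inflate the
configured mean by roughly a quarter.

The behavioural model generates, per participant: latent ability (additive
age, education and severity effects, a stroke deficit, and a subject-random
recovery slope on `log(1 + days)`); a lognormal motor response delay (median
300 ms, `sdlog` 0.55 — spanning ~120–740 ms of combined device and motor
latency); and a response-caution trait implementing the speed–accuracy
trade-off (+1 accuracy logit and +10% answer time per SD). Per trial,
accuracy is Bernoulli with a 1-parameter item-response form
(discrimination 1.3) and answer time is
`base·(1 + slope·b_c)·exp(−0.10·ability + 0.10·caution)` with lognormal
noise (`sdlog` 0.2). Using an impaired hand adds 150 ms of delay (×1.75 in
high motor-demand tasks), a 3% mis-tap rate in high-motor tasks, and — only
in the task explicitly designed to measure fine hand-motor ability — an
ability penalty. Impairment is assigned independently of latent ability:
motor impairment harms performance *only* through delay, mis-taps and
timeouts, which is precisely the confound the decomposition claims to
remove. MoCA-/IADL-like criteria are noisy rounded monotone maps of
session-level ability; imaging burdens are noisy decreasing functions of
baseline ability, with the white-matter noise component additionally loaded
onto attention/speed/memory tasks in the chronic phase (the planted
structure the CCA back-projection should recover).

Several generator choices deserve their rationale:

* **Task-specific ability variance** (`task_session_sd = 0.55`, implying
  between-task correlations near 0.6) makes the global factor explain
  60–70% of variance. An early, nearly-parallel-task configuration produced
  an unrealistic 82%; batteries of distinct cognitive domains do not behave
  like repeated measurements of one score.
* **Ceiling design**: low cognitive-demand tasks have condition difficulties
  far below typical ability, so healthy accuracy sits at ceiling and the
  graded information lives in response speed — the defining property of
  screening tasks, and the reason accuracy-only summaries lose information
  that the Cognitive Index retains.
* **Speed–accuracy trade-off**: the caution trait contaminates accuracy-only
  metrics (cautious responders look more able than they are) while the
  Cognitive Index, which multiplies accuracy by the speed of the cognitive
  response, partially cancels it.

What the generator does *not* emulate: device heterogeneity beyond an
additive latency, sequential/practice effects within a session, engagement
lapses and browser-interaction artefacts, task-flow gating in which harder
conditions are only reached by passing easier ones (the ability correction
is therefore exercised only mildly by the benchmark), non-independence of
impairment and ability, and real lesion anatomy (imaging is reduced to two
scalar burdens). Passing tests on this benchmark therefore demonstrates
internal consistency and confound-removal under the stated generative
assumptions, not clinical validity on real cohorts.

## What the benchmark shows

On the packaged benchmark (seed 1), asserted in the test suite and
recomputed by `scripts/acceptance.R`:

* estimated delays correlate ≥ 0.9 with the true motor delays, and scaled
  difficulties rank-correlate ≥ 0.9 with the designed condition difficulties
  in every task;
* the impaired-hand term is significant (across-task FDR q < 0.05) for
  accuracy and/or median RT in every high motor-demand task, and for the
  delay time in all of them, while the Cognitive Index shows no effect in
  any task except the designated motor task;
* under a null generator with every motor effect removed, confound verdicts
  occur at no more than the false-positive floor (50 replicate cohorts);
* the criterion R² of the global factor is strictly larger for the
  Cognitive Index family than the accuracy family in all three phases;
* mixed-model fixed-effect type-I error lies in [0.03, 0.07] at α = 0.05
  (100 null replicates), and CCA permutation p-values are uniform under
  independence (50 replicates, Kolmogorov–Smirnov at α = 0.01);
* every intermediate of the decomposition matches a hand-executed
  transcription of the formulas on a 3-participant × 2-condition toy table
  to 1e-12, and the EM-PCA, CCA, BH-FDR and Yeo–Johnson primitives match
  their independent oracles (classical PCA, `cancor`, brute-force step-up
  enumeration, closed-form branch values).

Simulation sizes in the suite (replicate counts, cohort sizes for the null
replicates, permutation counts) are chosen so the whole suite documents the
properties at standard desk scale; the acceptance script reruns the full
benchmark end to end.

## Known limitations

The delay/answer-time split leans on the difficulty gradient; in tasks with
nearly flat answer-time curves the session-level delay reverts to the mean
residual and absorbs cognitive slowing, so per-task delay estimates from
flat tasks should not be over-interpreted (pooling delays across the battery
is the robust summary). A fixed motor deficit that prevents most responses
outright leaves too little trial-by-trial variability for any trial-level
model — such sessions surface as low Cognitive Index with large delay, not
as a corrected score. The delay also absorbs any non-motor additive latency
(visual processing, device), so its interpretation as *hand*-motor delay is
contextual. Finally, whether delays should be estimated per task or pooled
per session across tasks is left open by design; the package computes them
per task (the unit at which confound results are reported) and exposes the
pooled mean through the decomposition table.
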