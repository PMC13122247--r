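---
title: "Models and methods behind gazemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazemeta analyzes two-task gaze-perception experiments: an *implicit* task
(object detection under task-irrelevant gaze, a naturalistic gaze-cueing
design) and an *explicit* task (deliberate judgment of the actor's gaze
target), with trial-by-trial confidence on an 11-point 0–100 scale and a
per-subject Autism-Spectrum Quotient (AQ) score. This vignette documents
the statistical models, the synthetic-data generator that stands in for
raw trial data, the tunable parameters, and the numerical and design
choices a user should know about.

## Accuracy models

Binary correctness is modeled with logistic mixed models (lme4, Laplace
approximation; adaptive Gauss–Hermite with a configurable node count is
available for intercept-only fits). Factors are coded numerically at model
time only — gaze validity 1 = valid / 0 = invalid, body-head congruency
1 = congruent / 0 = incongruent — so the stored labels can never silently
flip. For the implicit task (object-present trials only, obtained with
`filter_present_trials()`; object-absent fillers measure response bias,
not cue use):

$$\mathrm{logit}\,P(\text{correct}_{ij}) = \beta_0 + \beta_1 v_{ij} +
\beta_2 c_{ij} + \beta_3 v_{ij} c_{ij} + b_{0j} + b_{1j} v_{ij} +
b_{2j} c_{ij} + b_{3j} v_{ij} c_{ij}$$

The explicit task is entirely gaze-valid, so its model carries congruency
only, optionally with z-scored AQ and its interactions. Continuous
predictors are always z-transformed within the analysis sample; a
zero-variance covariate is an error, not a silent constant column.

**Random-effects policy.** The maximal specification (every within-subject
term as a correlated random slope) is frequently singular at 12 trials per
cell, so the default is a random intercept plus *uncorrelated* (diagonal)
random slopes, with `random = "maximal"` available where the richer
structure is estimable and `random = "intercept"` for speed in simulation
studies. `random = "none"` pins every variance at zero but still goes
through the mixed-model deviance machinery (theta fixed at 0), which is
what the degenerate-equivalence tests exercise against `glm()`/`lm()`.
Inference is Wald (z) for the logistic models and Satterthwaite-t
(lmerTest) for the linear confidence models. Non-convergence is flagged on
the returned object, never silently dropped; coefficients diverging beyond
|β| > 15 on the logit scale raise a separation diagnostic.

**Per-subject coefficients and the two-stage transfer.** A subject's
coefficient for a term is the fixed estimate plus their conditional mode
(BLUP) for the matching random slope. The two-stage analysis z-scores the
per-subject implicit validity-by-congruency coefficients and enters them
as a fixed covariate (`implicit_accuracy`) in the explicit model. The
paired comparison of implicit-interaction versus explicit-congruency
coefficients is a paired t with df = n − 1. Because BLUP shrinkage can
truncate a small slope variance to exactly zero (making the paired t
unidentified), `compare_subject_effects()` refuses to return a statistic
in that case and the pipeline falls back to the maximal structure for this
one stage.

## Confidence and the Type-2 ROC

Confidence ratings are z-standardized within task and regressed on
accuracy, z-scored AQ and their interaction, with a random intercept and
accuracy slope per subject (REML). Implicit-task confidence analyses use
the same object-present filter as the accuracy analyses, keeping the two
response models aligned on the same trials.

Metacognitive sensitivity is the criterion-sweep Type-2 ROC area. Each
grid value is taken in turn as the criterion separating low from high
confidence; for each criterion the hit rate P(high | correct) and
false-alarm rate P(high | incorrect) give one curve point, anchored by
(0,0) and (1,1), and AUROC2 is the trapezoidal area over the
false-alarm-sorted curve. For ratings on a shared grid this equals the
pairwise statistic — the fraction of (correct, incorrect) trial pairs in
which the correct trial has the higher confidence, ties counting 1/2 —
which the package implements separately (`auroc2_pairwise()`) as an
independent oracle; the test suite holds the two routes to within 1e-12.
Subjects with no correct or no incorrect trials have undefined AUROC2 and
are dropped from correlations with a recorded count.

The AUROC2–AQ association uses a tie-averaged-rank Spearman rho with the
t approximation (df = n − 2; an exact-style permutation p is available by
flag), computed with and without multivariate outliers flagged by squared
Mahalanobis distance on the (AQ, AUROC2) plane against the chi-square
(df 2) quantile. The screening variables and cutoff are configurable
because neither is canonical; the default alpha is 0.025. The AQ median
split assigns ties at the median to the low group and compares groups with
a Welch t test, reporting the two-sided p alongside the one-sided p for
the high-AQ group scoring lower.

## The synthetic generator

`generator_config()` defaults encode the study conditions the analyses
assume: 64 subjects; implicit task 96 trials per subject (12 object-present
trials per validity-by-congruency cell plus 48 object-absent fillers at a
fixed 95% correct-rejection rate); explicit task 96 gaze-valid trials, 48
per congruency level; integer AQ drawn as a rounded normal with mean 16.1
and SD 6.08, truncated to [2, 27]. Accuracy fixed effects default to
(1.01, 0.96, 0.99, −1.04) on the implicit log-odds scale and
(1.72, 0.07, −0.20, 0) for the explicit intercept, congruency, AQ slope
and congruency-by-AQ terms, producing the target pattern: a validity
benefit only under body-head incongruence, an inert explicit congruency
effect, and explicit accuracy declining with AQ.

Random structure: per-task subject intercept SDs of 0.5, and random slope
SDs of 0.3 (implicit validity, implicit congruency), 0.5 (implicit
interaction) and 0.2 (explicit congruency). The slope SDs are calibrated
from the spread of per-subject coefficients such a design reports: with
≈ 0.9 per-subject sampling error at 12 binary trials per cell, a BLUP SD
near 0.24 back-solves to a true interaction-slope SD near 0.5, and the
much tighter explicit spread to ≈ 0.2. A `transfer_coupling` parameter
(default 0: the tasks share no latent trait) adds a per-SD contribution of
the subject's implicit interaction deviation to explicit accuracy, for
studying the two-stage transfer under induced coupling.

Confidence arises from a latent variable
$\mu_0 + (s_0 + s_{AQ}\,z(AQ) + u_j)\,\text{correct} + b_j + \varepsilon$,
discretized by ten equal-width cuts (width 0.5, centered at 0) onto the
0–100 grid, i.e. 20 rating points per latent unit. Defaults: type-2
slopes $s_0$ of 1.66 (implicit) and 1.17 (explicit); $s_{AQ}$ = −0.25 in
the explicit task and 0 implicitly, so only explicit metacognitive
sensitivity declines with AQ; slope heterogeneity SD 0.3 per task, so
AUROC2 varies between subjects beyond AQ; latent intercepts −1.38 /
−1.00 and noise SDs 0.72 / 0.85, chosen so the latent scale is
approximately standardized given the tasks' accuracy levels and the
z-scored-confidence LMM recovers $s_0$ up to the discretization
attenuation. The magnitude of $s_{AQ}$ and the heterogeneity SDs are not
anchored to any reported generative model (none exists); they were fixed
once at values giving a moderate negative explicit AUROC2–AQ rank
correlation.

Reproducibility: every draw for subject *i* comes from a private stream
seeded by (base seed, *i*, stage), so identical configs and seeds give
byte-identical tables and *adding subjects never changes earlier
subjects' data*. To preserve that prefix-stability, the generator
standardizes AQ by the configured moments, while the fitted models
z-score within sample; the resulting estimand difference is far below the
sampling noise at these sizes.

**What the generator does not emulate.** Trials are exchangeable within
cell: no learning, fatigue, block structure or serial dependence; no
response times; confidence is conditionally Gaussian-latent rather than
skewed or end-anchored as real rating data often are; object-absent
accuracy is a flat rate rather than a signal-detection criterion; and the
observed AUROC2 levels run higher than typical empirical values because
the latent coupling is homogeneous and strong. Passing tests on this
generator therefore validate the statistical machinery and the direction
and approximate size of effects under the assumed model — not
distributional quirks of real behavioral data.

## Numerical choices and degenerate inputs

- lme4 defaults govern optimizer tolerances; derivative checks are
  disabled for the logistic fits (speed) and singular fits are permitted
  and flagged rather than erroring, since diagonal structures at 12
  trials/cell legitimately truncate small variances to zero.
- Confidence values are validated against the exact 11-value grid on
  load; off-grid values are row-indexed errors.
- Design imbalance is data (a violation list in the `design_report`),
  not an exception; an empty trial table yields a "no trials" violation.
- Ties: Spearman uses average ranks; the AQ median split sends ties at
  the median to the low group; AUROC2 ties count 1/2 in the pairwise
  oracle and are handled by the shared-grid sweep automatically.
- The Mahalanobis screen requires at least 3 points and a nonsingular
  sample covariance (reciprocal condition number above 1e-12).

## Problem sizes used by the test suite

Structural tests run reduced designs (4–24 subjects) for speed; the
statistical validation runs at the study size: 64 subjects and full trial
counts for single fits, 100 seeded replicates for coefficient recovery
(random-intercept fits, whose fixed effects are what recovery concerns),
1,000 subjects for AUROC2 oracle equivalence and null calibration, 500
replicates of n = 64 for the outlier-rate calibration, and 100 seeds for
the AUROC2–AQ sign recovery. The full suite and the acceptance script
each complete in minutes on one CPU.

## Known limitations

- The paired coefficient-comparison t is highly sensitive to how much
  between-subject spread the random-slope fit retains; under heavy
  shrinkage its magnitude is unstable (its sign and significance are
  not). Interpret the means and their difference, not the t's size.
- Satterthwaite df are reported for LMMs only; GLMM inference is Wald.
- No Bayesian estimation, no meta-d′-style model-based metacognitive
  efficiency, and no model selection: the model set is fixed by the
  design.
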