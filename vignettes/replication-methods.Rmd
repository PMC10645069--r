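---
title: "Models and methods for assessing replication study pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for assessing replication study pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replistat)
```

## The problem

Collections of original/replication study pairs — for example cohorts of
pedagogical replications, where each student re-implements one published
experiment — report their key statistics in heterogeneous forms:
per-condition means and SDs, t statistics, one-degree-of-freedom F
statistics, 2x2 proportion tables, or regression coefficients with
standard errors. To ask "did the replication succeed?" quantitatively, and
to ask *what predicts* success, these must first be placed on a common
scale, then compared with statistics that respect both studies' sampling
error. `replistat` implements that pipeline: effect-size derivation,
replication-consistency metrics, a descriptive layer, regularized Bayesian
regressions of replication success, and a ground-truthed synthetic
generator that makes every stage testable without access to any particular
coded dataset.

## Effect-size derivation

All two-group mean comparisons are expressed as standardized mean
differences (SMD). From summaries, Cohen's
$d = (\bar{x}_1 - \bar{x}_2)/s_p$ with the pooled SD, and
$\mathrm{SE}(d) = \sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$. From a
between-participants $t$: $d = t\sqrt{1/n_1 + 1/n_2}$. From a paired $t$:
the change-score effect $d_z = t/\sqrt{n}$. One-df F statistics convert via
$|t| = \sqrt{F}$, with the direction supplied by a separately coded
same-direction flag, since F carries none. Proportion tables become log
odds ratios (0.5 continuity correction when a cell is empty) and reported
coefficients stay on their native scale; both support the consistency
metrics but not SMD-based comparisons, which is why the analysis subsets
nest (all pairs ⊇ pairs with comparable estimates ⊇ pairs with SMDs).

Two derivation choices are genuinely open and documented as package
decisions:

* **SMD variant.** Uncorrected Cohen's d, no Hedges small-sample
  correction. Conventional for this style of analysis; medians of SMDs may
  move at the second decimal under other variants.
* **Within-participants standardization.** Change scores ($d_z$), because
  $d_z$ is computable from the reported $t$ and $n$ alone; raw-score
  standardization would need the cross-condition correlation, which reports
  almost never contain. Accordingly, the `means_within` schema route
  defines its mean/SD fields as the mean and SD *of the paired
  differences*.

p-values are always recomputed from the statistics rather than read from
text (reported p-values are frequently truncated, e.g. "p < .001").
Estimates are aligned so the original is non-negative and the
replication's sign follows the coded direction flag; p-values are computed
before alignment and are sign-invariant.

## Replication-consistency metrics

For a pair with estimates $\hat\theta_o, \hat\theta_r$ and standard errors
$se_o, se_r$ on a shared scale:

* **Prediction interval.**
  $\hat\theta_o \pm z_{0.975}\sqrt{se_o^2 + se_r^2}$ — the interval
  expected to contain a consistent replication's point estimate 95% of the
  time. A z (not t) quantile is used because many statistics only recover
  an estimate and SE, not raw degrees of freedom; at the sample sizes
  involved the difference is negligible and the z form keeps the metric
  defined for every route.
* **p-original.**
  $p = 2\{1 - \Phi(|\hat\theta_r - \hat\theta_o| /
  \sqrt{\tau^2 + se_o^2 + se_r^2})\}$, the two-sided p-value on the
  hypothesis that both estimates share one underlying effect, optionally
  inflated by a between-implementation heterogeneity SD $\tau$.
* **Consistency at $\tau$.** The binary rule
  $p_{\mathrm{orig}}(\tau) \ge 0.05$, with $\tau = 0.21$ SMD as the
  conventional average multi-site heterogeneity level. The thresholded
  form is our operationalization of "distributionally consistent"; it is
  the standard construction in the prediction-interval framework.

At $\tau = 0$ and level 0.95, interval membership and
$p_{\mathrm{orig}} \ge 0.05$ are the *same* z statistic thresholded at
1.96 — the suite asserts this duality exactly on 1,000 random pairs.
Subjective replication scores on the grid $\{0, 0.25, 0.5, 0.75, 1\}$ are
remapped to ordinal levels 1–5 for modelling.

On cohorts, summaries always report explicit fractions (e.g. "45%
(61/136)") rather than independently rounded percentages, so a
numerator/denominator is never displaced by a re-rounded abstract-style
figure (46% vs 61/136 = 44.9% is the canonical example of why).

## Predictor coding

The design matrix codes: subfield dummies with cognitive psychology as the
reference; 0/1 flags for open data, open materials, Stanford affiliation,
within-participants design (mixed designs count as within), and single
vignette; `switched_to_online` = 1 only for in-person originals with
online replications (in-person replications join the "no change" group);
natural logs of trials, original n, and the replication/original n ratio;
publication year; and optionally the original SMD and log original
p-value. Continuous columns are z-scored after the log transforms so the
shrinkage prior regularizes them comparably; dummies stay 0/1. Natural
logs are used throughout (the base is irrelevant after z-scoring). Rows
with missing demographic predictors are dropped with a warning naming
them — in the motivating cohort exactly one pair is in that state, and how
it was handled upstream is not recoverable, so the package makes the
exclusion explicit and logged.

## Bayesian models

Three outcome models share one prior structure:

* ordinal (cumulative logit) for the 1–5 subjective score,
* logistic for prediction-interval membership,
* linear (identity link) for p-original.

Fixed effects get a horseshoe prior: $\beta_j = z_j \lambda_j \tau_g$ with
$z_j \sim N(0,1)$, local scales $\lambda_j \sim t^+_{3}(0,1)$ and global
scale $\tau_g \sim C^+(0,1)$ — the three-df local/half-Cauchy-global
mixture conventionally written "horseshoe(3)". A regularized variant with
a fixed slab scale is available (`slab_scale`); the slab is not sampled,
which keeps the gradient simple and is sufficient for the stated use
(guarding against separation). Cohort (class-year) random effects are
included for the intercept and every predictor, non-centred, each SD with
a half-normal(0, 0.5) prior. No interaction terms.

**Deliberate deviation: independent rather than LKJ-correlated random
slopes.** The conventional specification correlates the random slopes with
an LKJ(1) prior. LKJ(1) is flat over correlation matrices, and with ~12
cohort levels against a dozen predictors those correlations are barely
identified — the data contribute almost nothing beyond the prior. Because
the package ships its own gradient-based sampler (no external MCMC backend
is assumed), the Cholesky-factor transform and its gradient would be the
single riskiest piece of code in the package for essentially no inferential
gain, so random effects are modelled independently. `lkj_shape` is accepted
for interface compatibility and warns when set away from 1.

Whether a random intercept accompanies the slopes is similarly unstated in
convention; one is included (for the ordinal model it acts as a cohort
shift of all cutpoints).

p-original is modelled on its raw (0,1) scale, matching the conventional
analysis; a Gaussian on a probability is a known misfit, so the fit
reports (never clamps) the number of fitted values escaping (0,1).

**Sampling.** Models are estimated with a built-in no-U-turn sampler:
dual-averaging step-size adaptation (target acceptance 0.9), windowed
diagonal mass-matrix estimation, slice-based tree building with a
divergence flag at energy error > 1000. All scale parameters are sampled
on the log scale; ordered cutpoints as first-cutpoint + log-gaps; random
effects non-centred — the standard funnel mitigations. Gradients are
hand-derived and verified against finite differences in the test suite;
the sampler itself is validated on exact Gaussian targets. Convergence
policy (ours; no convention exists to inherit): split-Rhat ≤ 1.01 on every
reported coefficient, with one automatic retry at doubled length and
higher `adapt_delta`, then a loud error; effective sample size below
`ess_min` and any divergence produce warnings. Posterior summaries are
medians with central 95% credible intervals, exponentiated to odds ratios
for the logit links.

## The synthetic world

`simulate_pairs()` states the generator's world once:

* design mixes matching the motivating cohort's descriptive table (45%
  within-participants, 44% single vignette, 40% social psychology, 30%
  open data, 53% in-person-to-online switches, median n ratio 0.86);
* true effects: 30% exact nulls, the rest
  $N(0.25 + 0.25\,\mathrm{within} + 0.15\,\mathrm{cognitive} -
  0.10\,\mathrm{single\ vignette},\ 0.30^2)$ — chosen once as a plausible
  psychology-literature mix producing median observed original SMDs near
  0.6 after selection;
* publication selection: originals are redrawn until two-sided p < 0.05,
  which *creates* winner's-curse inflation rather than asserting it;
* heterogeneity: the replication's true effect is the original's plus
  $N(0, \tau^2)$, default $\tau = 0.21$;
* sampling error via the actual reporting routes (noncentral t draws,
  chi-squared SD noise, binomial tables), so derived estimates inherit
  realistic non-normality; emitted statistics are rounded to 6 significant
  digits, mirroring reporting precision and making CSV round-trips exact;
* subjective scores from an ordered-logit over the same design features
  plus an evidence term, so model recovery is well-posed, with the
  generating coefficients returned as ground truth.

What the generator does **not** emulate: coder disagreement, closeness
judgments tied to actual procedures (closeness is drawn independently),
publication-year trends, or any correlation between design features. A
green test therefore establishes that the *machinery* is correct under the
stated world, not that the world matches any particular literature.

`coverage_experiment()` deliberately bypasses the reporting routes and
draws estimate/SE pairs directly from the normal model, because its
purpose is calibration of the metrics themselves (coverage exactly 95% at
$\tau = 0$, p-original exactly uniform); the reporting-route
non-normality is a property of the generator, not of the metrics.

`recovery_experiment()` plants coefficients in GLM-style simulated
matrices rather than routing through the replication machinery for the
logistic/linear outcomes — interval membership and p-original generated by
the full machinery have no closed-form true coefficients, so "recovery"
would be undefined. The ordinal route through `simulate_pairs()` is
additionally exercised end-to-end in the test suite (sign recovery of
planted score-model coefficients). "~95% CrI coverage" is operationalized
*before measurement* as: pooled coverage ≥ 0.90 across 48 datasets (null
coefficients legitimately overcover under shrinkage — a horseshoe CrI
concentrated at zero almost always contains zero), sign recovery ≥ 0.90
for the strong planted effects, and at most 2 non-converged datasets per
family (non-convergence is reported, never skipped).

## Numerical choices

* Quantiles: type-7 (linear interpolation) by default and configurable;
  IQR endpoints are mildly sensitive to the choice and no convention is
  stated for the motivating tables.
* Continuity correction: 0.5 added to all four cells of a proportion
  table only when a cell is zero.
* Degenerate inputs: zero SDs, empty subsets, off-grid scores, and
  non-positive SEs raise typed errors; per-row validation returns issue
  lists rather than raising, so one bad row never hides the rest.
* Tie-breaks: PI membership uses closed intervals; the exact-duality test
  pins the boundary convention to the p-original threshold.
* Byte-stable CSV: numbers are written with up to 15 significant digits;
  combined with 6-digit generator rounding, write → read → write is
  byte-identical, which the pipeline's digest-based cache relies on.

## Known limitations

* Random-slope correlations are not modelled (see above).
* The horseshoe global scale is fixed at the unit half-Cauchy; no
  effective-nonzero-count calibration is exposed.
* Conversion routes exist only for the statistic types listed; correlation
  coefficients, PCA outcomes and multi-df omnibus tests are out of scope
  by design (they were uncodable upstream too).
* The paper-number reproduction checks require the externally deposited
  coded dataset, which is not redistributable; without it those checks
  fail with instructions rather than silently passing (see
  `inst/extdata/osf/README.md`).
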