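---
title: "Scoring the HEI-NVS and analysing its course in a two-arm trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the HEI-NVS and analysing its course in a two-arm trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heinvs)
```

## The index

The Healthy Eating Index-NVS is the German adaptation of the Healthy Eating
Index family, built for the National Nutrition Survey II. It scores a
seven-day food diary against the food-group recommendations of the German
Nutrition Society (DGE): ten components — fruits, vegetables, grains, dairy,
fish, beverages, meat, eggs, spreadable fats and alcohol — each earn points
from the subject's mean daily intake, and the total, the plain sum of the
components, ranges from 0 to 110. Fruits and vegetables carry a maximum of
15 points each, the remaining eight components 10. A diary meeting every
recommendation scores the full 110.

Components come in two directions. *Adequacy* components (vegetables,
fruits, grains, dairy, fish, beverages) reward intake proportionally up to
the reference amount and are capped there:

$$\text{points} = \text{max} \times \min(1,\ \text{intake}/\text{reference}).$$

*Moderation* components (meat, eggs, spreadable fats, alcohol) keep the full
score at or below the reference and lose points linearly, reaching zero at
`zero_point_multiple` times the reference (default 2). Both branches are
continuous and piecewise-linear, so the total is continuous in every intake.

The published scoring standards live in an appendix we do not reproduce;
the two anchors stated outright — 400 g/day of vegetables and 250 g/day of
fruit — are built in, and the remaining reference amounts are DGE-plausible
defaults (e.g. 30 g/day fish as roughly two portions a week, 1.5 L/day of
beverages, 10 g/day alcohol). Because the exact published cut-points may
differ, the entire table ships as data (`default_reference_table()`) and as
an editable YAML file (`inst/extdata/reference_table.yaml`): dropping in a
different published standard requires no code change. Sex-specific
references (common for alcohol in German indices) are not modelled; the
table is sex-agnostic.

Two dietary quantities accompany the score. *Energy density* is the energy
per gram of consumed food, computed over the whole diary with beverages
excluded from both numerator and denominator — the standard convention in
energy-density research, available behind the `include_beverages` flag.
*Energy intake* is total diary energy over observed days. Beverages and
alcohol are recorded in grams with density 1 g/mL assumed.

Mapping raw food names to components is out of scope: diary rows arrive
already labelled with a component (or `"other"`, which counts only toward
energy). The trial's nutrition software performed that assignment; no
food-composition database is bundled here.

## The trial analysis

The package reproduces the analysis pipeline of a two-arm randomized trial
of web-based weight-loss programs (interactive, energy-density-focused
intervention vs. informational control; examinations at baseline, after the
12-week program, and at 6- and 12-month follow-up).

**Imputation.** The primary analysis is intention-to-treat: all randomized
subjects, missing follow-ups multiply imputed (50 imputations in the study;
drivers accept smaller m for quick passes). The imputer is single-level
chained equations on the subject-wide layout: each incomplete
variable-timepoint column is regressed on group, the same variable at the
other timepoints (its baseline is always complete) and the concurrent
diet-quality context (`hei_nvs_total`, `energy_density`). Draws are
predictive mean matching with a donor pool of 5 — robust to the bounded,
non-normal score margins — with fully parametric Bayesian-normal draws
behind a flag; imputed component scores are clamped to their range. The
study itself used a multilevel imputation package; conditioning on the
subject's own other timepoints plays the role of the subject-level effect
here. Imputed totals are not constrained to equal the sum of imputed
components; each variable is imputed on its own, as in the study's
variable-wise imputation. Pooling follows Rubin's rules with the
Barnard–Rubin small-sample degrees of freedom.

**Robust linear mixed model.** The HEI-NVS total is modelled with fixed
effects for time (three contrasts against baseline), group (control against
intervention) and their interactions — exactly eight coefficients — plus a
subject random intercept. Robustness is by iteratively reweighted maximum
likelihood: after each weighted fit, conditional residuals are scaled by
their MAD and turned into Huber weights $w=\min(1, 1.345\,s/|e|)$, until the
largest relative coefficient change falls below 1e-8 (at most 100
iterations). Numerical choices worth knowing: the random-intercept variance
ratio is profiled with Brent's method per iteration and held fixed once it
stabilises, because its optimiser noise (~1e-7) would otherwise mask
coefficient convergence; the MAD, an order statistic, is likewise frozen
after 20 iterations. With all weights forced to 1 the fit reproduces the
`lme4` maximum-likelihood solution to ~1e-12 (a test asserts this). The
study used a different robust estimator (DAStau); equivalence is claimed,
and tested, only in the clean-data limit — at realistic noise the two
estimators differ by a random O(n^{-1/2}) amount even when both are
correct, which is why the oracle-equivalence test runs at residual SD 0.01
where the 0.1% per-coefficient agreement isolates the algorithm rather
than sampling noise. P-values are Wald with a normal reference for single
fits (robust mixed models lack exact small-sample df) and pooled-t for
multiply imputed fits.

**Effect sizes.** Within-group Cohen's d is the mean change from baseline
divided by the SD of the change scores (the study does not state its
formula; baseline-SD standardization sits behind a flag), with the
normal-approximation interval $d \pm z_{0.975}\sqrt{1/n + d^2/(2n)}$, and
the usual 0.2 / 0.5 / 0.8 reading.

**Associations.** For each variable and each interval (t1 − t0 and
t3 − t0), the Pearson correlation between change in the HEI-NVS total and
change in the variable is bootstrapped by resampling all subjects with
replacement (B = 5000 in the study) and given a bias-corrected percentile
interval: $z_0$ is the normal quantile of the fraction of bootstrap
replicates below the point estimate, and endpoints sit at the bootstrap
quantiles $\Phi(z_0 + (z_0 \pm z_{\alpha}))$, interpolated between order
statistics on the normal-quantile scale. "Bias corrected" is read as plain
BC; the accelerated BCa variant (jackknife skewness) sits behind a flag and
is cross-checked against the `boot` package in the tests. How the study
combined bootstrap intervals across 50 imputations is not stated; here each
cell pools on the Fisher-z scale — mean z as the point, per-imputation
interval offsets averaged and inflated by the Rubin total-to-within
variance ratio — and the same resampling indices are reused across
imputations of a cell, so identical datasets collapse exactly to the
single-dataset interval. No multiplicity correction is applied across the
26 cells (the study applied none); a Benjamini–Hochberg pass is a
one-liner on the output if wanted.

## The synthetic trial

The original data are not released, so the generator is the package's
test-bed and demonstration substrate. Its defaults *are* the study
conditions: 153 subjects, 1:1 permuted-block randomization with block sizes
2/4/6, per-arm component-score means and SDs at each timepoint matching the
published descriptives, baseline BMI 30.71 (SD 2.13), age 48.92 (11.17),
71.2% women, and monotone dropout whose per-stage logistic hazard
(depending on baseline BMI and group under MAR; MCAR available) is
recalibrated each stage so the cumulative dropout is 22.9% in expectation
regardless of the covariate coefficients.

Component scores are Gaussian draws around the configured trajectories with
a shared subject-level deviation (within-subject correlation 0.5, a typical
diet-record test-retest value) and are clamped to their score range; the
HEI-NVS total is their sum. Clamping is unavoidable — several published
SDs sit right at the boundary (spreadable fats 9.83 (0.82)) — and it pulls
means a few points toward the interior: the simulated baseline total is
~73 rather than ~76. The clamp count is reported (`n_clamped`) rather than
hidden.

The non-score variables are built as baseline plus change: change-score
correlations, not raw-measure correlations, carry the configured structure,
because the association analysis operates on changes. The configured
matrix's ΔHEI row (energy density −0.30 by default, in the range of the
published associations; weak entries elsewhere) is induced by
standardizing each subject's realized ΔHEI against the sample and drawing
the other deltas conditionally; the matrix is validated symmetric,
unit-diagonal and positive semi-definite. Baseline levels of the
cardiometabolic variables are plausible values for adults with overweight
(e.g. energy density 1.65 kcal/g, energy intake 2100 kcal/d, total
cholesterol 210 mg/dL); the arms' change means encode a modest weight loss
with partial regain, slightly larger under the interactive program.

Diaries are synthesised by inverting the scoring rules: adequacy intakes
proportional to the score, moderation intakes through the piecewise-linear
inverse (full scores placed at the reference), weekly amounts spread over
the seven days with Gamma-weighted day variation that preserves the weekly
total exactly, and a residual `"other"` food per day absorbing the energy
and mass needed to hit the record's energy-intake and energy-density
targets at typical food-group energy densities. Re-scoring an emitted
diary reproduces its target component scores to ~1e-14. Energy targets
that a record's component foods make impossible (a drawn energy intake
below the foods' own energy, or an energy density above what the foods can
reach) are nudged to the nearest attainable value in panel and diary alike
and counted (`n_energy_adjusted`); with the defaults this touches a
minority of records, mostly high-score/low-intake draws.

What the generator does **not** emulate: day-of-week and seasonal eating
patterns, underreporting (a known feature of self-reported diaries in this
population), digit preference, item-level diary structure beyond one entry
per component per day, non-monotone missingness, and any engagement
mechanism behind the arm differences — the trajectories simply encode the
outcome. Tests passing on this generator therefore certify the *pipeline*
(scoring arithmetic, imputation machinery, estimator behaviour,
interval calibration), not conclusions about real dietary data.

## Problem sizes and reproducibility

The test suite and drivers scale the expensive stages to sizes a laptop
handles comfortably while keeping every estimate's Monte-Carlo error well
inside its acceptance band: parameter-recovery and robustness simulations
use 200 replicates at n = 150; bootstrap calibration uses 1500 replicates
at n = 153 with B = 1000 (B = 5000, the study value, is the driver default
for the single analysis run); the end-to-end smoke run uses m = 10
imputations. Every random stage takes an explicit seed, and the pipeline
derives logged sub-seeds from one master seed; identical configuration and
seed reproduce every table byte for byte.

## Worked example

```{r example, eval = FALSE}
library(heinvs)

sim <- simulate_trial(sim_config(), seed = 1)
run <- run_trial_analysis(sim_config(), seed = 1, m = 10, B = 1000)
run$model_table      # Table-2 shape: 8 coefficients, SE, p
run$effect_sizes     # Table-4 shape: d with 95% CI per group and interval
run$correlations     # Table-5 shape: r with BC 95% CI per variable/interval
```

The numbered scripts under `analysis/` run the same stages one at a time
and narrate what they find.

## Known limitations

* The exact published component standards are approximated by a
  config-driven linear table; results with the true appendix table require
  editing one YAML file.
* The robust estimator is a Huber-IRLS scheme, not the study's DAStau; the
  two agree on clean data but can differ under heavy contamination.
* Wide-format single-level imputation stands in for the study's multilevel
  imputation; with only four timepoints and baseline conditioning the
  practical difference is small, but it is a documented divergence.
* Component-score truncation biases simulated means toward the interior of
  the score range (about 3 points on the total at baseline).
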