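---
title: "Validating tissue oximeters against weighted blood references: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tissue oximeters against weighted blood references: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxival)
```

## The measurement problem

A NIRS tissue oximeter reports StO₂, the oxygen saturation of a
microvascular mixture of venous and arterial blood. There is no gold
standard that measures the same quantity directly, so validation studies
compare the device against a weighted combination of co-oximetry
saturations from drawn blood,

$$\mathrm{REF} = r_v\,\mathrm{SvO_2} + (1 - r_v)\,\mathrm{SaO_2},$$

with the venous weight $r_v$ conventionally set to 0.70 (a 70:30
venous:arterial volume ratio). Data come from a stepped-hypoxia protocol:
each subject completes one room-air plateau and eight hypoxia plateaus
(pulse-oximetry targets spanning 100–70%), with one arterial/venous blood
draw per plateau shared by all sensor sites. Nine points per subject means
every downstream statistic must respect within-subject dependence; that is
the organizing principle of this package.

## Agreement statistics

**Bias and precision.** `bland_altman()` reports the mean and sample SD of
the device-minus-reference differences. With repeated measures the naive SD
mixes within- and between-subject variation with weights set by the design,
so `bland_altman_repeated()` decomposes the differences
$d_{ij} = \mu + b_i + e_{ij}$ with one-way ANOVA moment estimators
(unbalanced clusters handled through the usual $n_0$ coefficient of the
expected mean squares) and reports
$\sqrt{\hat\sigma^2_{b} + \hat\sigma^2_{w}}$ as the modified precision.
Moment estimators were chosen over likelihood because they are closed-form
and hand-checkable; a negative between-subject moment estimate is truncated
at zero, in which case the modified SD can sit marginally below the
standard SD. Precision is reported as 1 SD, with ±1.96 SD limits of
agreement available as a secondary field.

**Subgroups.** Skin-tone rows (light/moderate/dark, mapped from
self-reported race as White→light, Asian/Hispanic→moderate, Black→dark)
and site rows reuse the same machinery. Group contrasts use a Welch t-test
on *per-subject mean differences* — one value per subject — rather than on
pooled points; pooled points would overstate the effective sample size
ninefold. This is a package decision: the convention in validation reports
("t-test for means") does not specify the unit, and the subject-level
choice is the conservative one.

## The two-step pooled Deming analysis

Each subject's nine points get a Deming errors-in-variables fit with
error-variance ratio $\lambda$ (y-error variance over x-error variance,
default 1):

$$\hat\beta_1 = \frac{S_{yy} - \lambda S_{xx} +
\sqrt{(S_{yy} - \lambda S_{xx})^2 + 4\lambda S_{xy}^2}}{2 S_{xy}},
\qquad \hat\beta_0 = \bar y - \hat\beta_1 \bar x.$$

At $\lambda = 1$ this is orthogonal regression — identical to the first
principal axis of the centered scatter, which the test suite exploits as an
independent oracle. Coefficient SEs come from the delete-one jackknife
within subject (implemented by downdating the moment sums, so the $n$
refits cost one pass). Per-subject estimates are then pooled across
subjects by inverse-variance meta-analysis: Cochran's Q assesses whether
the per-subject coefficients are homogeneous, and the default
DerSimonian–Laird random-effects weights $1/(se_i^2 + \hat\tau^2)$ absorb
genuine subject-to-subject differences in the device's response; a
fixed-effect variant is available. Random effects are the default because
subject heterogeneity is the rule, not the exception, in this design.

Subjects contributing fewer than 4 points, or whose series is exactly
collinear (jackknife SE 0, which would receive infinite weight), are
excluded with a warning. The fully degenerate case — every subject on one
common line — is detected and pooled exactly (Q = 0, zero-width CIs).

### What the λ = 1 estimand is, and when it is not the device slope

$\lambda$ encodes a belief about how measurement error splits between the
reference and the device. When the truth is y-only noise (an error-free
reference), the $\lambda = 1$ estimand is the principal-axis slope, which
exceeds the generating slope by approximately
$\sigma_e^2 / (2\sigma_x^2)$ — about +0.02 to +0.03 at this package's
default simulation scale (residual SD 2.5%, reference spread SD ≈ 10%).
That shift is comparable to the pooled SE at 25 subjects, so a recovery
experiment that pairs the default generator (which places all noise on the
device side) with $\lambda = 1$ will *not* attain nominal CI coverage for
the generating slope, at any sample size. This is a property of the
estimand, not an implementation defect: the same pooled machinery achieves
nominal coverage when the simulation places equal error on both axes (see
the matched-error recovery and bootstrap-calibration tests). Users running
simulation studies should set $\lambda$ to the error-variance ratio their
generator actually implies; for real co-oximetry-referenced data, where
both sides carry error of broadly similar scale, $\lambda = 1$ remains the
sensible default and is what the package records in every report.

## Random-coefficients model and CCC

`random_coefficients_fit()` fits
$y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) x_{ij} + e_{ij}$ by REML
(`lme4`), with an unstructured 2×2 random-effects covariance; singular
fits are refitted with independent random effects, with a warning, and a
degenerate (zero-residual) fit reports fixed effects with NA SEs rather
than failing. Wald 95% CIs use the 1.96 multiplier, matching the
lower/upper-confidence-limit table convention of validation reports.

`ccc()` reports two estimators. The naive Lin CCC
$2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ comes with its
delta-method SE and a Fisher-z CI. The default headline estimator accounts
for repeated measurements per subject through a variance-components model
on the stacked readings,
$value = \mu + \beta_{method} + u_{subject} + u_{subject:pair} + e$, giving

$$\mathrm{CCC} = \frac{\sigma^2_{subj} + \sigma^2_{pair}}
{\sigma^2_{subj} + \sigma^2_{pair} + \sigma^2_{e} + d^2/2},$$

which reduces to the population value of Lin's CCC under the exchangeable
model ($d$ is the fixed method difference). Its SE uses a
delete-one-subject jackknife. The literature offers several
repeated-measures CCC estimators (variance components, U-statistics); the
variance-components form was chosen for transparency and because its
population target coincides with Lin's. Within bootstrap replicates the
naive estimator is used: subject-block resampling already carries the
dependence structure, and the variance-components refit would add three
orders of magnitude of cost for no change in the resampling distribution's
target.

## Bootstrap validation

Two schemes validate the regression and CCC estimates:

- **Bootstrap I** resamples whole subjects with replacement. Each drawn
  subject contributes its intact 9-point series, so within-subject
  correlation is preserved without being modelled.
- **Bootstrap II** (double bootstrap for panel data) resamples subjects,
  then resamples each drawn subject's ordered series with overlapping
  moving blocks — all contiguous windows of length $b$ with overlap
  $b - 1$, drawn with replacement, concatenated, truncated to the original
  length. The block size follows the cube-root rule $b = \lceil n^{1/3}
  \rceil$ clamped to $[2, n]$: a 9-point series gives $b = 3$, overlap 2
  (7 windows). The ceiling form is used because it reproduces the
  conventional choice of 3 at $n = 9$ while giving 2 at $n = 8$ and 3 at
  $n = 27$. The assembly rule (draw $\lceil n/b \rceil$ blocks, truncate)
  is a package decision; the literature leaves it open.

Each `bootstrap_validate()` call uses one explicitly seeded RNG stream,
with the subject draw preceding the within-subject draws in fixed order,
so results are exactly reproducible. Reported intervals are the normal
approximation ($\hat\theta \pm 1.96\,se_{boot}$) and the bias-corrected
percentile interval (BC, not BCa — no acceleration term), with
$z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$ clamped away from
±∞ when all replicates fall on one side. BC bounds are actual order
statistics of the replicates (type-1 quantiles). Replicates where a refit
is degenerate are dropped and counted; more than 10% failures aborts with
diagnostics. B defaults to 500.

## The V:A ratio uncertainty sweep

Because REF is linear in $r_v$, recomputing the Bland–Altman bias at
another venous weight obeys the exact identity

$$bias(r_v) = bias(0.70) + (0.70 - r_v)\,\overline{\mathrm{SaO_2} -
\mathrm{SvO_2}},$$

i.e. roughly 0.30% of bias per one-point ratio shift when the mean
arteriovenous difference is ~30%. `va_ratio_sweep()` recomputes the full
pipeline per ratio and `implied_bias()` is the closed form; a test asserts
their agreement to 1e−8 on any dataset. The sweep reports
reference-minus-device differences, so a smaller venous weight (a more
arterial, hence higher, reference) yields a more positive bias — the
direction such sweeps are conventionally tabulated in. The headline
Bland–Altman tables use device-minus-reference; both conventions are
explicit arguments and the report metadata records them.

## The synthetic study generator

`simulate_study()` emulates exactly the structure the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| plateau targets | 98, 94.5, …, 70 (%) | room air then even steps to the 70% protocol floor; interior values are an artifact choice, the protocol fixes only span and count |
| AV difference mean ± SD | 30.15 ± 6.17 (%) | published cohort scale for the arteriovenous saturation gap |
| venous weight $r_i$ | 0.70 ± 0.033 | subject-level mixing ratio; ±10% of the ratio at 3 SD, the plausibility bound usually argued for inter-subject V:A variability |
| device slope / intercept | 1.0 / 0.0 (%) | ideal device unless the experiment injects miscalibration |
| subject offset SD | 1.5 (%) | between-subject device offset |
| residual SD | 2.5 (%) | per-reading device noise; with the offset this yields ~3% total device-vs-reference SD, the cerebral precision scale |
| SaO₂ jitter SD | 1.0 (%) | plateau-control imprecision around the target |
| cohorts | 25 cerebral / 24 somatic | published cohort sizes; skin-tone counts 15/5/5 and 8/2/14 |

Per subject $i$, plateau $j$: $SaO_{2,ij} = target_j + N(0, jitter)$;
$SvO_{2,ij} = SaO_{2,ij} - AV_{ij}$ with $AV_{ij}$ normal truncated at 0;
true tissue saturation $T_{ij} = r_i SvO_{2,ij} + (1-r_i) SaO_{2,ij}$;
device reading $a + o_i + b\,T_{ij} + N(0, \sigma_e)$. All saturations are
clipped to [0, 100] *after* noise and clipping events are counted in the
truth record. Somatic sites share the plateau's blood draw and $T_{ij}$
and receive independent device noise. Sensor side alternates with subject
parity (13/12 split at n = 25). ETCO₂ control is modelled only implicitly,
as a constant within-subject $r_i$; no CO₂ covariate is generated.

What the generator deliberately does **not** emulate: respiratory
physiology (no inspired-gas → SpO₂ dynamics), within-plateau time series,
co-oximeter analytical error (the recorded SaO₂/SvO₂ *are* the truth —
see the λ discussion above for what this implies for recovery
experiments), site-specific physiology beyond shared blood values, and
any skin-tone-dependent device behaviour (tone groups differ only by
labels, so tone contrasts are null under the generator). Passing tests on
simulated data therefore demonstrate correctness of the statistical
machinery under the stated model, not device performance on real tissue.

## Numerical choices and degenerate inputs

- Deming: vertical (constant-x) data and the $S_{xy} = 0$,
  $S_{yy} = \lambda S_{xx}$ orientation are typed errors; $S_{xy} = 0$
  with $S_{yy} < \lambda S_{xx}$ returns the horizontal axis (slope 0).
  Two points are accepted for the line itself; the jackknife requires 4.
- Jackknife delete-one subsets that become degenerate raise an error
  naming the offending index.
- REML fits: convergence left to `lme4` defaults with derivative checks
  disabled for speed; singular fits fall back as described.
- CSV round trips are value-exact: saturations serialize at 17
  significant digits.
- Physiological inversions (SvO₂ > SaO₂) are warnings, never errors,
  since co-oximeter noise can produce them near full saturation; rows are
  retained and flagged in the load report.
- Validation-suite problem sizes (the package's own choices): 50 seeded
  studies for parameter recovery, 200 outer replications at B = 200 for
  bootstrap-coverage calibration, 4000 Monte-Carlo studies against the
  chi-square law for the power analysis, 100 random instances for the
  Deming/principal-axis equivalence.

## Power for a precision claim

`precision_power()` simulates clustered differences with total SD
`true_sd` split by an explicit intraclass correlation and reports the
probability that the pooled sample SD falls at or below a threshold. At
ICC 0 this matches the closed form
$P(S \le t) = F_{\chi^2}\big((n-1)t^2/\sigma^2;\, n-1\big)$
(`precision_power_exact()`), and increasing ICC at fixed total SD widens
the observed-SD distribution — the familiar "80% chance of observing
≤ 3.8% when the truth is 3%" style statement is only meaningful once the
clustering assumption is stated, which is why ICC is a required, visible
parameter here rather than a hidden constant.

## Known limitations

- No weighted Deming with per-point variance functions, no Passing–Bablok
  alternative, and no proportional-bias (bias-vs-mean trend) modelling.
- The variance-components CCC assumes exchangeable pairs within subject;
  strong serial correlation along the plateau sequence would be absorbed
  into the pair component rather than modelled.
- Bootstrap II's moving-block scheme assumes the plateau sequence is the
  meaningful serial order; studies with randomized plateau order should
  use Bootstrap I.
- The generator's truth record makes recovery experiments easy, but the
  estimand caveat for λ under one-sided noise applies to any
  errors-in-variables method, not just this implementation.
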