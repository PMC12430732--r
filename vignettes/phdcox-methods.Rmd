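---
title: "Methods: diet scores, composite genetic risk and Cox models in phdcox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet scores, composite genetic risk and Cox models in phdcox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdcox)
```

phdcox implements the full analysis chain of a prospective
diet-and-cancer cohort study: a planetary health diet (PHD) adherence
score, a composite cancer polygenic risk score (CPRS), an auditable
cohort exclusion cascade, and sex-aware Cox proportional-hazards
analyses with spline dose-response and joint gene-diet stratification.
Because individual-level biobank data cannot be redistributed, the
package ships a synthetic cohort generator whose defaults emulate the
design of a large UK cohort (recruitment 2006-2010, administrative
censoring on 2022-05-31, roughly 46% men, about 8.7% cumulative cancer
incidence over a median 13 years of follow-up). Every analysis stage is
validated by parameter recovery on that generator.

## The PHD score

Fourteen dietary components are each scored 0-10 and summed to a 0-140
total. Intakes are first normalised to a 2500 kcal/day reference
energy, `intake * 2500 / energy`, so the score reflects dietary
composition rather than total consumption. Three rule classes are used:

* **Adequacy** (vegetables, fruits, nuts, fish, legumes, unsaturated
  fats): `10 * min(1, intake / T)`. The score is linear through the
  origin - zero intake is non-adherence and scores 0 - and saturates at
  the recommended amount `T`.
* **Balanced** (whole grains, dairy, eggs, potatoes, poultry): a tent
  function `10 * max(0, 1 - |intake - T| / T)`, peaking at the target
  and losing half the marks at 50% or 150% of it. A tent is the only
  piecewise-linear rule in which deviations below and above the target
  produce proportional deductions, which is why this class - sometimes
  called the "optimum" group - is scored this way.
* **Moderation** (saturated fats, red meat, added sugars):
  `10 * max(0, 1 - intake / L)`, full marks at zero intake and none at
  or beyond the limit `L`, with no tolerance band before the decline.

The default reference amounts in `phd_rules()` follow the EAT-Lancet
2500-kcal reference diet (vegetables 300 g/d, fruits 200 g/d, legumes
75 g/d, nuts 50 g/d, fish 28 g/d, whole grains 232 g/d, dairy 250 g/d,
red meat 14 g/d, ...). They are deliberately a configurable table, not
constants baked into the scoring code: analyses that use different
cut-off conventions can pass a modified table to `compute_phd()` and
the sensitivity suite exposes a pluggable rule-set hook. All structural
tests are symbolic in `T`/`L`, so correctness does not depend on these
defaults. Participants with several 24-hour assessments are averaged
component-wise (`average_assessments()`) before scoring.

Two useful invariances follow from the construction and are tested:
multiplying every intake and the energy by one constant leaves all
scores unchanged, and the total is a continuous piecewise-linear
function of each intake, bounded in [0, 140].

## Site PRS and the composite CPRS

For each cancer site *k*, the polygenic risk score of participant *i*
is the additive dosage model `PRS_ik = sum_j dosage_ij * beta_jk`. The
composite score weights sites by their population burden:
`CPRS_i = sum_k h_k * PRS_ik`, with `h_k` the age-standardised
incidence of site *k* (cases per 100 000 person-years) in the
participant's sex; sex-specific sites (breast-like, prostate-like)
enter only their own sex's sum.

Site PRS are z-standardised within sex *before* weighting. Raw PRS
scales depend arbitrarily on how many variants a site's panel happens
to contain and on the units of its effect sizes; without
standardisation a site with many weak variants could dominate or vanish
regardless of its incidence. Standardising first makes `h_k` the sole
importance weight, which is the behaviour the composite is meant to
have. This is a deliberate design choice of the package; analyses that
want the raw weighting can pass raw values to `compute_cprs()`
directly. Note that group assignment - the quantity that drives all
downstream analyses - is a rank statistic of CPRS within sex, so it is
insensitive to the `h_k` scale (per 100 000 versus proportions) and to
any monotone rescaling of the composite.

Genetic risk groups are CPRS quintiles within sex: low (Q1),
intermediate (Q2-Q4), high (Q5). Quintile boundaries put ties in the
lower group, the same convention used everywhere else in the package.

## Exclusion cascade and analysis variables

`apply_exclusions()` applies the selection rules in a fixed flowchart
order - cancer at baseline, no dietary questionnaire, non-European
ancestry, missing polygenic-score inputs, withdrawn or lost to
follow-up, implausible energy intake (men <800 or >4000 kcal/day,
women <500 or >3500 kcal/day, judged on the mean energy across
assessments) - attributing each removal to the *first* matching rule,
as selection flowcharts report. Retention itself is a set difference,
so permuting the rules changes the audit counts but never the surviving
cohort; both facts are asserted in tests. `build_flowchart_fixture()`
provides a deterministic 502 411-record cohort whose flags reproduce a
published selection flowchart exactly (44 825 / 265 106 / 9 169 /
3 611 / 11 / 2 248 removed; 177 441 retained), which pins down the
cascade arithmetic.

The PHD exposure enters models two ways: quintiles (Q1 reference) and
per 1-SD, standardised with the sample SD (n-1). Main-analysis
quintiles are computed on the pooled analysis sample; the joint
15-group analysis recomputes them within sex, since that analysis is
defined sex-separately. Categorical covariates keep an explicit
"unknown" level rather than being imputed or dropped, mirroring how
cohort baseline tables report missingness. The adjustment sets are
`crude` (none), `model1` (age, sex, BMI, energy, 10 genetic principal
components) and `model2` (model1 + income, education, Townsend index,
alcohol, smoking, family history of cancer).

## The Cox engine

`cox_ph()` maximises the Efron-corrected partial likelihood by
Newton-Raphson (C++ core). Convergence requires the largest score
component below 1e-8 or a relative log-likelihood change below 1e-10;
step halving guards against overshooting. Efron's tie correction is the
default and only method because follow-up recorded in coarse units
produces ties, and Efron is the standard recommendation. A monotone
likelihood (a coefficient drifting past 15 with a non-vanishing score,
as happens under perfect separation) is flagged `converged = FALSE`
with a warning rather than silently returned; rank-deficient designs
are rejected naming the collinear columns. Wald confidence intervals
are `exp(beta +/- 1.96 SE)`.

The proportional-hazards check (`cox_zph()`) is the Grambsch-Therneau
score test: each covariate column `x` is augmented by `x * g(t)` with
`g` a centred transform of event time (default the left-continuous
Kaplan-Meier scale `1 - S(t-)`), and the score test of the augmented
coefficients uses the full extended information matrix. Per-covariate
and global statistics are reported with Efron-consistent risk-set
means. On shared datasets the engine and this test agree with the
long-established `survival` implementations to 1e-6 (coefficients) and
1e-4 (p-values); that package is used in the test suite as an
independent oracle only, never as the implementation.

Dose-response uses a restricted cubic spline (`rcs_dose_response()`):
4 knots by default at the 5/35/65/95 percentiles (Harrell's
convention), truncated-power basis scaled by the squared boundary-knot
span, exactly linear beyond the boundary knots. Nonlinearity is a
likelihood-ratio test of the nonlinear basis columns (k-2 df), and the
reported curve is anchored at log HR 0 at the reference exposure
(default the median). Trend tests are Wald tests of integer-coded
ordered groups - the paperwork-standard "P for trend" - rather than
quintile-median coding; with five roughly equal groups the two codings
are nearly affine, and integer coding keeps the test exact under
permutation of labels.

One numerical safeguard applies across suite fits: a dummy column whose
carriers (or non-carriers) contain no events has an infinite
coefficient MLE and contributes a singular direction to the
information. Such columns - in practice tiny "unknown" covariate levels
in small strata - are merged into the reference level by dropping them
from the design. Exposure columns are never dropped. The engine
additionally falls back to a symmetric pseudo-inverse if the
information matrix is numerically singular mid-iteration, so monotone
directions cannot abort an otherwise well-posed fit.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

**Covariates.** Age ~ N(56.3, 8.1) truncated to 37-73; BMI and energy
log-normal around medians 26.25 kg/m2 and 2008 kcal/day; Townsend index
normal around -2; ten standard-normal genetic principal components;
categorical covariates (income, education, smoking, alcohol, family
history) drawn at the marginal frequencies of a large UK cohort's
baseline table, including explicit "unknown" levels at their reported
(sub-percent to 10%) rates. The Townsend distribution is modelled
symmetric although the real one is right-skewed; nothing downstream
depends on that skew.

**Diet.** Each participant completes 0-5 assessments
(probabilities 0.05/0.43/0.24/0.14/0.09/0.05; the zero class feeds the
"no questionnaire" exclusion). Component intakes are zero-inflated
log-normal - never-consumer probabilities reproduce the many zero
medians cohort intake tables show for nuts, fish, eggs, poultry and
added sugar - with a shared latent "diet quality" factor loading
positively on plant foods and negatively on red meat and added sugar.
That one factor induces the joint gradient across score quintiles seen
in real baseline tables. Medians are calibrated so that, e.g., median
vegetable intake lands within 10% of 284.75 g/d.

**Genotypes.** Dosages are binomial(2, MAF) with MAF uniform on the
configured range, independent across variants - no linkage
disequilibrium or ancestry structure, which the analyses do not use.
The default desk-scale panel is 20 sites x 10 variants; the weight
table format accepts any panel. Incidence weights default to a
synthetic table spanning 10-170 cases per 100 000 with one female-only
and one male-only site, so sex-restricted site lists are exercised.

**Survival.** Event times are exponential proportional hazards,
`T ~ Exp(h0 * exp(eta))`, with entry dates uniform over the recruitment
window and administrative censoring at the censor date. A constant
baseline is chosen deliberately: Cox estimation is invariant to the
baseline shape, and the constant form gives closed-form cumulative
incidence `1 - E[exp(-h0 e^eta T_admin)]` that both the calibration
root-finder (`calibrate_baseline_hazard()`, monotone in `h0`, achieved
incidence within 1e-6 of target) and its tests exploit. Deaths and
loss to follow-up are not simulated as competing risks - only
administrative censoring - matching the analysis model, which treats
them as absent.

**Effects.** The generating linear predictor adds covariate effects
(age 0.07/yr, male log 1.35, smoking, family history, BMI, deprivation
- all absorbed by the adjusted models) to one configured exposure
truth: per-SD PHD log(0.96); CPRS group contrasts (men log 1.54 /
log 2.50, women log 1.26 / log 1.72); or additive joint 15-group
effects parameterised by a per-quintile PHD step and a CPRS level
chosen so the (Q5 PHD, low CPRS) versus (Q1 PHD, high CPRS) contrast
equals the configured extreme value (men log 0.39, women log 0.55).
Only one exposure truth is active per scenario so that each recovery
target estimates the parameter it injects: hazard ratios are
non-collapsible, and a strong unadjusted second exposure would
attenuate the marginal estimate of the first.

Named RNG streams (covariates / diet / genotypes / survival) derive
from the scenario seed, so changing one block never perturbs another,
and identical configurations are byte-identical.

**What passing recovery shows - and what it does not.** The generator
matches the analysis model by construction (log-linear effects,
exponential baseline, independent censoring), so parameter recovery
validates the estimation machinery, not the robustness of the design to
confounding, measurement error in 24-hour recalls, competing mortality
or linkage-disequilibrium structure, none of which are simulated.

## Problem sizes and numerical choices

Validation runs use cohorts of 50 000 (test suite) to 200 000
(acceptance script) participants - large enough that the Monte-Carlo SE
of a per-SD log hazard ratio is below 0.01 while a full pipeline run
stays in the tens of seconds. Calibration of the two specification
tests (proportional hazards, spline nonlinearity) uses 500 null
replicates of n = 2 000, which bounds the simulation SE of a 5%
rejection rate at about 1 percentage point. Quintile ties break to the
lower group everywhere; type-7 empirical quantiles are used, whose
interpolated cuts fall strictly between order statistics so group
membership is invariant under monotone transforms of the exposure.

## Known limitations

The moderation rule has no "minimal intake" tolerance band and the
adequacy rule passes through the origin; if a convention with plateaus
near zero is wanted, it must be expressed through a modified rule
table. The exclusion cascade consumes an ancestry flag, it does not
infer ancestry. No multiple-testing correction is applied across
suites. The joint suite reports NA rows for empty cells rather than
merging them. Subgroup strata with no events return NA rows. The
generator's dietary energy is only weakly linked to the component
intakes, so energy adjustment in the score is exercised but not
stress-tested against strong intake-energy confounding.
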