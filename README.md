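# phdcox

Tools for prospective diet-and-cancer cohort analyses, built around
three questions: does adherence to the planetary health diet (PHD)
relate to overall cancer incidence, does that relation differ by sex,
and how does it combine with polygenic cancer risk?

The package is aimed at epidemiologists who want the whole analysis
chain as tested, reusable functions rather than one-off scripts:

* **PHD scoring** — the 14-component, 0–140 adherence score. Each
  component intake is normalised to a 2500 kcal/day reference
  (`intake × 2500 / energy`) and scored 0–10 by one of three rules:
  adequacy `10·min(1, x/T)`, balanced (tent) `10·max(0, 1 − |x−T|/T)`,
  moderation `10·max(0, 1 − x/L)`. Multiple 24-hour assessments are
  averaged per participant.
* **Genetic risk** — per-site additive polygenic risk scores
  `PRS_ik = Σ_j dosage_ij β_jk`, z-standardised within sex and combined
  into an incidence-weighted composite `CPRS_i = Σ_k h_k PRS_ik`
  (with `h_k` the site's age-standardised incidence), then grouped by
  within-sex quintiles into low / intermediate / high genetic risk
  (20 / 60 / 20%).
* **Cohort pipeline** — a six-rule exclusion cascade with a
  first-match audit trail, quintile and per-SD exposure derivation, and
  assembly of analysis datasets for three adjustment models (crude;
  model 1: age, sex, BMI, energy, 10 genetic principal components;
  model 2: + income, education, Townsend index, alcohol, smoking,
  family history).
* **Survival models** — an Efron-tie Cox partial-likelihood engine
  (`cox_ph()`, Newton–Raphson, C++ core) with Schoenfeld
  proportional-hazards score tests (`cox_zph()`), restricted cubic
  spline dose-response with a nonlinearity LRT, ordinal trend tests,
  and the main / joint-15-group / subgroup / sensitivity analysis
  suites.
* **Synthetic cohort generator** — draws covariates, right-skewed
  correlated dietary intakes, binomial genotype dosages and exponential
  proportional-hazards event times with administrative censoring, so
  the full pipeline can be exercised and validated by parameter
  recovery without access to individual-level biobank data.

## Worked example

Simulate a cohort of 30 000 under the default scenario (per-SD PHD
effect HR 0.96, ~8.7% cumulative incidence) and run the main analysis:

```r
library(phdcox)
cfg <- scenario_config(n_participants = 30000, seed = 42,
                       effect_set = "phd")
st  <- simulate_study(cfg)
st$audit
#>                       rule entering removed remaining
#> 1          baseline_cancer    30000     601     29399
#> 2 no_dietary_questionnaire    29399    1540     27859
#> 3    non_european_ancestry    27859     541     27318
#> 4         missing_prs_data    27318     278     27040
#> 5         lost_to_followup    27040       2     27038
#> 6       implausible_energy    27038     116     26922

run_main_suite(st$data, sex = "all", model = "model2")
#>     term     n events    hr ci_low ci_high      p p_trend p_nonlinearity ph_global_p
#>  phd_qQ1  5385    495 1.000  1.000   1.000     NA      NA             NA          NA
#>  phd_qQ2  5384    483 0.958  0.845   1.087 0.5073  0.0384             NA          NA
#>  phd_qQ3  5384    468 0.928  0.818   1.054 0.2504  0.0384             NA          NA
#>  phd_qQ4  5384    448 0.881  0.775   1.001 0.0521  0.0384             NA          NA
#>  phd_qQ5  5385    450 0.897  0.789   1.019 0.0959  0.0384             NA          NA
#>    phd_z 26922   2344 0.955  0.917   0.994 0.0246      NA          0.851       0.291
```

Reading the report: the five quintile rows contrast PHD quintiles
against Q1 (reference HR fixed at 1) with their group sizes and event
counts; `p_trend` is the ordinal trend test across quintiles. The
`phd_z` row is the per-SD continuous effect — here HR 0.955
(CI 0.917–0.994) against a generating truth of 0.96 — with the spline
nonlinearity p-value (0.851: no curvature, as simulated) and the global
Schoenfeld proportional-hazards p-value (0.291: no violation, as
simulated). `run_joint_suite()` produces the 15-row PHD-quintile ×
genetic-risk-group table against the (Q1, high-risk) reference, and
`run_subgroup_suite()` / `run_sensitivity_suite()` the stratified and
robustness refits.

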