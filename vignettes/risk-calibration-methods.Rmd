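---
title: "Methods: validating Cox-form CVD risk equations in cohorts with severe mental illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating Cox-form CVD risk equations in cohorts with severe mental illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Absolute cardiovascular-disease (CVD) risk equations drive primary-prevention
decisions: a person's 5-year risk determines whether lipid-lowering or
blood-pressure treatment is recommended. These equations are Cox-form models
fitted to large primary-care cohorts, and they predict well *on average* — but
people treated by specialist mental health services (here called the SMI
group, ascertained from service-contact records rather than diagnoses) carry
CVD risk beyond what their measured risk factors explain. An equation without
a mental-illness predictor will then systematically underestimate their risk.

`cvdcalib` implements the full validation pipeline needed to quantify that
underestimation, together with a synthetic linked-cohort generator so that
every stage is testable end to end without access to any (non-releasable)
patient-level data:

1. **Synthetic cohort generation** — linked person and service-contact tables
   with a configurable sex-specific excess event risk in the exposed group.
2. **Risk scoring** — absolute 5-year risk from a declarative, sex-specific
   Cox-form equation specification.
3. **Cohort construction** — the eligibility cascade (age 30–74, no prior
   CVD/heart failure/renal failure, complete smoking and cholesterol data),
   exposure ascertainment from contacts, and prioritised ethnicity.
4. **Observed risk** — Kaplan–Meier estimates with Greenwood variance, and
   directly age-standardized cumulative-incidence curves by exposure group.
5. **Calibration** — observed:predicted comparison in deciles of predicted
   risk, summarised by the mean ratio across deciles.

## The risk model

For a person of sex $s$ with predictor vector $x$, the linear predictor is

$$\mathrm{LP} = \sum_j \beta_{sj}\,(x_j - c_{sj}) + \text{interactions},$$

with centring constants $c_{sj}$, and the absolute risk at the horizon $h$
(5 years by default) is

$$\;R(h) = 1 - S_{0s}(h)^{\exp(\mathrm{LP})},$$

where $S_{0s}(h)$ is the sex-specific baseline survival at the horizon (the
survival of a person whose LP is zero). Equations are *data, not code*: a
JSON/YAML document lists terms (identity, log, or indicator transforms with a
source column and level), coefficients, centring values, optional pairwise
interactions, and $S_0(h)$. Production coefficient sets can therefore be
dropped in without touching the package. The bundled default
(`default_risk_equation()`, also shipped as
`inst/extdata/equation-default.json`) is **illustrative only**: its
coefficients have plausible epidemiological magnitudes (e.g. log-hazard
≈ 0.07–0.08 per year of age, ≈ 0.5–0.6 for current smoking or diabetes) and
its baseline survivals (0.979 women, 0.968 men) were chosen so a 30–74-year
primary-care cohort gets typical 5-year risks of about 1–15% with means near
the 3–5% event fractions seen in such cohorts. They are not the coefficients
of any published production equation.

## What the generator emulates

Defaults of `sim_config()` encode the study conditions the package targets:

* **Exposure structure.** 5.8% of persons have a qualifying (inpatient or
  face-to-face community) mental-health contact in the 5 years before index;
  15.5% of the exposed carry a functional-psychosis diagnosis (ICD-10
  F20–F31); diagnosis codes are missing completely at random at the contact
  level with probability 0.362. Because psychosis coding is near-complete in
  routine practice, each psychosis person is guaranteed at least one surviving
  F20–F31-coded contact; without that guarantee the configured psychosis
  fraction could not be recovered from the released tables.
* **Decoy contacts** exercise the ascertainment filter: stale contacts (more
  than 5 years before index), non-face-to-face (`setting = "other"`) contacts
  inside the window, and post-index contacts, none of which may confer
  exposure.
* **Risk factors** are drawn per sex-by-exposure stratum with the magnitudes
  typical of such cohorts (the exposed are younger, more deprived and smoke
  roughly twice as much; most other factors are similar between groups); see
  `default_strata()`. Values are recorded at clinical precision (integer
  mmHg, 1-dp BMI, 2-dp TC:HDL, 1-dp age), which also makes the CSV exchange
  format lossless.
* **Follow-up.** Administrative censoring at `min(12.2` years`,` study end
  `-` entry`)`, plus independent non-CVD death at a constant hazard of
  0.004/year. Entry is staggered with *accelerating* accrual:
  entry $= W\,U^{0.64}$ for $U \sim \mathrm{Unif}(0,1)$ over the
  $W = 12.2$-year window. Uniform accrual cannot reconcile a 12.2-year
  maximum with a ≈ 4.5-year mean follow-up (its mean is at least half the
  window), whereas a risk-assessment programme whose uptake grows over time
  naturally concentrates entries late; the shape 0.64 solves
  $W\,p/(p+1) \approx 4.7$ years of mean administrative follow-up, leaving a
  realized mean of about 4.5 years after events and deaths truncate some
  follow-up.
* **Outcomes.** The baseline survival is Weibull-extended from the horizon,
  $S_0(t) = S_0(h)^{(t/h)^k}$ with shape $k = 1$ (constant baseline hazard)
  by default, and event times are drawn by inverse-transform sampling. In
  `risk_ratio` mode (the default) an exposed person's true cumulative risk is
  $\min\{1, m\,[1 - S_0(t)^{\exp(\mathrm{LP})}]\}$ with $m$ the sex-specific
  excess factor (defaults 1.64 for women, 1.29 for men), so the
  observed:predicted ratio equals $m$ *by construction* — the mode used for
  parameter-recovery testing. `hazard_ratio` mode, where $m$ multiplies
  $\exp(\mathrm{LP})$, is the mechanistically more conventional alternative;
  on the risk scale the two coincide only as risks $\to 0$.
* **Filter fodder.** About 5.3% of generated persons fall outside 30–74
  years, 12% carry a prior-CVD flag and 1.2% a renal-failure flag; smoking,
  cholesterol and BMI are masked with the configured missingness *after*
  outcome simulation (the generating process scores complete records).

What the generator does **not** emulate: correlation between age and risk
factors within a stratum; secular trends in risk-factor levels or treatment;
emigration (folded into administrative censoring); hospitalisation coding
streams; or any dependence of censoring on covariates. Passing
parameter-recovery tests therefore shows the *estimator chain* is correct
under clean study conditions, not that any particular real equation is
miscalibrated.

## Design choices on genuinely open points

* **Age eligibility** is completed age 30–74, i.e. $30 \le \text{age} < 75$
  at index; both endpoints inclusive in completed years.
* **Exclusion order** is age → prior CVD/renal → missing smoking → missing
  cholesterol, each person counted once at the first rule failed, so the flow
  table telescopes exactly.
* **Exposure window** is half-open: $[\text{index} - 5\text{y},
  \text{index})$, with the gap measured in exact days/365.25. "Prior to" the
  assessment means same-day contacts never qualify.
* **Psychosis subgroup**: any F20–F31 code on any contact — any setting, any
  date including post-index (routine diagnoses accumulate after the index
  assessment and near-complete psychosis coding is worth more than temporal
  purity here). Matching is on the two-digit family; sub-codes after the
  decimal are ignored; malformed codes are warned about and treated as
  missing, never fatal.
* **Age adjustment**: the method behind published "age-adjusted" incidence
  curves is often unstated. We use direct standardization over the 10-year
  bands 30–44/45–54/55–64/65–74 with the whole eligible cohort as the
  reference, for transparency and testability: the adjusted incidence is a
  weighted average of band-specific Kaplan–Meier incidences, its variance the
  weight-squared combination of Greenwood variances (delta method, normal
  interval on the incidence scale, clipped to $[0,1]$). An empty
  group-by-band cell contributes no incidence and is flagged — preferable to
  silently renormalising weights, because it biases the adjusted curve
  downward *visibly* rather than changing the estimand.
* **Deciles** are formed by ranking on (risk, person id) — the id making
  tie-breaks stable and order-free — with rank $r$ of $n$ assigned decile
  $\lceil 10r/n \rceil$, so sizes differ by at most one. Deciles are computed
  within each analysis population separately (exposure group, and sex where
  sex-specific tables are reported); combined-sex tables pool the population
  before forming deciles.
* **The mean ratio** is the unweighted arithmetic mean of the 10 per-decile
  observed:predicted ratios; the person-weighted mean is also emitted for
  comparison but is not the headline statistic. The ratio direction is
  observed/predicted, so values above 1 quantify underestimation. A
  zero-event decile reports ratio 0 and is flagged rather than dropped.
* **Confidence bands** for survival use the log(−log) transform (bounded in
  (0,1)); the observed-risk interval is the complement of the survival
  interval.
* **Degenerate inputs**: a population below 10 persons cannot be deciled and
  is reported with an explicit `insufficient` flag by the pipeline; a query
  beyond the last follow-up time returns the last estimate flagged as
  extrapolated; `risk_at(·, 0)` is 0 by the right-continuity convention.

## Reproducibility and numerical conventions

All randomness flows from the single config seed through stage-specific
derived seeds, so identical `(config, seed)` pairs regenerate byte-identical
tables and pipeline bundles (verified by hashing in the test suite). Dates
are ISO-8601; all durations are exact days/365.25. Recorded follow-up is
truncated (not rounded) to $10^{-4}$ years so it can never exceed the
administrative horizon. Configs and equations round-trip through JSON
losslessly (and through YAML at 15 significant digits).

## Problem sizes

The test suite exercises the estimator chain at $n$ = 200–30,000 and the
parameter-recovery checks at $n$ = 50,000 per sex, where the Monte-Carlo
standard error of the recovered mean ratio is ≈ 0.04–0.05 — comfortably
inside the ±0.08 band used for the recovery checks. The acceptance script
re-runs the recovery at $n$ = 50,000 and the follow-up calibration at
$n$ = 100,000. These sizes were chosen so each end-to-end run completes in
seconds while leaving recovery tolerances several Monte-Carlo standard
errors wide.

## Known limitations

* The bundled equation is illustrative; conclusions about any real equation
  require loading its actual specification.
* `risk_ratio` mode makes the mean ratio identifiable by construction; real
  excess risk need not act multiplicatively on the risk scale, and the
  `hazard_ratio` alternative will not recover $m$ exactly on the risk scale.
* Kaplan–Meier "observed risk" censors non-CVD death rather than treating it
  as a competing risk, matching the validation design it implements; it
  estimates net (hypothetical-world) risk, which exceeds crude cumulative
  incidence when competing mortality is non-trivial.
* Direct standardization with the eligible cohort as reference is one of
  several defensible weightings; group contrasts, not absolute adjusted
  levels, are the interpretable output.
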