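---
title: "Modeling the impact of opioid agonist treatment on suicide mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the impact of opioid agonist treatment on suicide mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatimpact)
```

## The estimation problem

Opioid agonist treatment (OAT) lowers suicide risk while a person is in
treatment, but a treatment program's population-level effect depends on how
much person-time the program actually covers, how risk differs between
prison and community settings, and how deaths are attributed between
overdose and suicide. This package chains two analyses:

1. estimate, from episode-structured cohort data, the on/off-OAT suicide
   incidence rate ratio (IRR) per setting and the proportion of non-overdose
   deaths attributable to suicide per stratum; and
2. push those estimates through a calibrated compartmental model of the
   OAT-ever cohort to compare the with-OAT baseline against a no-OAT
   counterfactual, yielding suicides averted, percent reduction, and
   life-years gained with credible intervals.

## Cause-of-death classification

A death is *overdose-related* if any of its ICD-10 codes (underlying or
additional) has a stem in T40.0–T40.6, T42.4, T42.6, T42.7, T43.6. Among
non-overdose deaths, a *suicide* is an underlying cause in X60–X84 or Y87.0
(sequelae of intentional self-harm). Everything else is *other
non-overdose*. Codes are normalized by upper-casing and stripping dots
before stem comparison. Two consequences of this ordering are worth
stating: a suicide by opioid poisoning (X6x with an opioid T-code) counts as
overdose, not suicide — suicides live strictly within the non-overdose
category — and the overdose check uses *all* listed codes while the suicide
check uses the underlying cause only.

## Person-time and the day grid

All dates are whole days and all intervals are half-open `[start, end)`.
Follow-up runs from the later of the study start and the person's first OAT
episode, to the earlier of the study end and death. Person-years are
days/365.25. The death day contributes no exposure but determines the
death's stratum: a state (OAT, incarceration) is considered held on the
death day if an episode spans it, starts on it, or ends exactly on it. The
last clause matters because episode records are truncated at death, so a
death in mid-episode leaves an episode ending on the death day; treating
that as active keeps generated deaths attributed to the stratum whose hazard
produced them. The one ambiguous case — an episode that genuinely ended the
same day the person died of something else — is resolved in favor of the
episode state; at day granularity the two are indistinguishable. A person
who dies on their entry day contributes zero person-time but one death,
attributed on-OAT (their first episode starts that day); such a person
retains a one-day sentinel episode in the generated tables so that every
cohort member has at least one OAT episode.

Incarceration takes precedence in defining the setting axis; OAT status is
evaluated independently on the same day. Off-OAT person-time is not censored
after long treatment gaps; `allocate_person_time()` works from the episode
tables as given, so a sensitivity analysis that truncates gaps can be run by
editing the tables upstream.

## Rate statistics

The IRR uses the Wald interval on the log rate ratio,
`exp(ln IRR ± z·sqrt(1/s_on + 1/s_off))`, the standard person-time
construction whose CI is symmetric on the log scale. When either arm has
zero events, 0.5 is added to both counts and the estimate is flagged; the
prison arm of a realistic cohort is sparse enough for this to matter.
Proportions use the Wilson score interval, which behaves sensibly at the
small denominators the prison strata produce (it never escapes [0, 1] and
has no zero-width degenerate case at 0 or n).

## The synthetic cohort generator

Real linked administrative data of this kind are not redistributable, so
`generate_cohort()` produces episode tables with the statistical structure
the downstream analysis assumes:

- **Entries**: `n_entrants` people (default 46,845) enter uniformly over the
  entry window (default August 2001 – December 2017); age at entry is
  log-normal matched to a median of 32 with IQR 26–39.
- **OAT engagement**: alternating exponential episode and gap lengths
  (defaults: mean 600 and 365 days — episode durations of this order are
  typical of large methadone/buprenorphine programs), with probability 0.8
  of returning after each gap.
- **Incarceration**: a Poisson process (default 0.1 events/person-year) with
  exponential spell lengths (mean 120 days), independent of the OAT process;
  overlapping spells are merged.
- **Deaths**: competing exponential clocks on each stratum interval of the
  person's timeline — memoryless piecewise-constant hazards for suicide,
  overdose, and other causes. The on-OAT suicide hazard equals the off-OAT
  hazard times a configurable IRR (defaults 0.32 community, 0.34 prison).
  Default off-OAT suicide hazards are 1.1/1000 PY (community) and 2.5/1000
  PY (prison), magnitudes consistent with a cohort of ~47k people accruing a
  few hundred suicides over 17 years. Other-cause hazards are back-solved so
  that suicides form 10/13/21/36% of non-overdose deaths in the
  community-on/community-off/prison-on/prison-off strata; because competing
  constant hazards split causes proportionally, those fractions hold exactly
  in expectation regardless of the overdose hazard.

Death causes are emitted as ICD-10 codes drawn from small per-cause pools.
By default no suicide carries an opioid T-code; `allow_suicide_overdose =
TRUE` tags a fifth of suicides with one for robustness checks of the
classification ordering.

What the generator deliberately does **not** emulate: within-person frailty
(hazards are homogeneous within a stratum), dependence between
incarceration and treatment state, seasonality or period effects, covariates
(sex, age-varying risk, socio-economic position), and linkage error. Tests
passing on this generator therefore demonstrate that the estimators recover
the parameters of a correctly specified episode process — not that they are
robust to confounding or misclassification in real administrative data.

## The compartmental model

`simulate_cohort()` integrates a seven-compartment deterministic model:
community on-OAT, recent-cessation (off, elevated overdose risk),
off-OAT, post-release on- and off-OAT (elevated overdose risk), and prison
on/off-OAT. This is the smallest structure that realizes initiation, ongoing
treatment, discontinuation, incarceration stratification, and both
elevated-risk windows. People enter at first OAT initiation (annual entry
series, spread uniformly within each year) and leave only through overdose
or other-cause death; "other-cause" includes suicide, which is carved out
later by the suicide fractions.

Key defaults (all rates per person-year): cessation 0.61 (the reciprocal of
a ~600-day mean episode), re-entry 0.80, incarceration 0.08 on / 0.12 off,
release 3.0 (a ~4-month mean spell), elevated-risk windows of 4 weeks with
overdose multipliers 4 (post-cessation) and 8 (post-release). The windows'
duration is a modeling choice — the literature supports a sharply elevated
overdose risk in the first weeks after release or cessation — and the
multipliers are deliberately exposed as calibratable parameters.

Numerics: fixed-step forward Euler with `dt` at most one week (default
1/52 year). The update is linear, so mass balance (entries − deaths =
population) holds to machine precision by construction, and a step is
rejected with a "use smaller dt" error if any compartment's total outflow
rate times `dt` exceeds 1 — the regime where Euler could produce negative
occupancies. Halving the step changes cumulative 20-year deaths by well
under 0.1% at default magnitudes (tested), so weekly resolution is adequate;
a daily step reproduces the closed-form exponential decay of a pulse to
within 0.5% over five years.

## ABC-SMC calibration

The sampler is generic over a simulator closure, with uniform or
log-uniform priors. Design choices, all conventional for ABC-SMC and all
config-exposed: distance = weighted mean squared relative error across the
annual calibration metrics (absolute error on a configured scale where the
observed value is zero); adaptive tolerance = the 0.5 quantile of the
previous generation's accepted distances (strictly decreasing by
construction); perturbation = component-wise uniform kernel of half-width
0.68 × the weighted standard deviation on the (log-)transformed scale,
reflected at the prior bounds. The importance-weight denominator uses the
*reflected* kernel density (direct image plus both boundary mirror images);
with a plain box kernel the weights are biased near the bounds, which is
detectable as an excess of boundary mass when the tolerance is forced to
infinity — the infinite-tolerance run must reproduce the prior, and the test
suite checks exactly that with a weighted Kolmogorov–Smirnov statistic.
One master seed derives per-generation child seeds, so runs are reproducible.
Desk-scale defaults are 200 particles × 5 generations; the pipeline demo
uses 100 × 3.

## Scenarios and uncertainty propagation

Per posterior particle: simulate, accumulate other-cause deaths per stratum
over the analysis years, multiply by per-stratum suicide fractions, divide
on-OAT suicides by the setting IRR for the counterfactual, and form averted
= counterfactual − baseline, percent = averted/counterfactual, life-years =
averted × (median age at other-cause death − median age at suicide; defaults
47 and 39). Estimation uncertainty in the IRRs and fractions is propagated
by default — log-normal draws matched to the IRR's CI, Jeffreys-beta draws
from the fraction counts — because the scenario intervals should reflect
parameter as well as calibration uncertainty; `freeze_uncertainty = TRUE`
holds both at their point estimates. Summaries are weighted medians and
weighted 2.5/97.5 percentiles. Note that medians of sums need not equal sums
of medians: per-draw identities (off-OAT invariance, additivity of averted
counts) hold exactly in every draw and are asserted there, not on the
summaries. With a protective community IRR the overall averted count is
positive in every draw; the prison contribution can be negative in draws
where the sampled prison IRR exceeds 1, reflecting the genuinely weak
evidence a sparse prison arm provides.

Internal arithmetic is unrounded; only printed reports round counts to
integers and percentages to whole percent.

## Pipeline scale and runtime choices

`demo_config()` runs the whole chain on 8,000 entrants with 100 particles ×
3 generations, which completes in seconds and yields a cohort ~170× smaller
than a state-wide program: absolute counts are small and credible intervals
wide, but the mechanism and all per-draw invariants are exercised. The test
suite sizes its simulation studies similarly — e.g. 100 replicate cohorts of
42,000 entrants for IRR coverage (giving > 200,000 person-years per
community arm), 500 replicates for Wald-interval coverage, 200-particle
ABC runs — sizes chosen so each study is statistically informative while the
whole suite stays comfortably interactive.

## Known limitations

- The scenario logic assumes the IRR is constant over calendar time and
  identical for recently released and other community person-time.
- The compartmental model has no aging, no cohort attrition other than
  death, and no entry outside first OAT initiation, so it speaks only to the
  OAT-ever population.
- The IRRs are unadjusted rate ratios; confounding by factors associated
  with both treatment retention and suicide risk is not addressed, and the
  synthetic generator cannot surface it.
- The prison arm is sparse by construction (few events), so prison-setting
  conclusions carry wide intervals at any realistic scale.
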