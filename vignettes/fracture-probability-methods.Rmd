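---
title: "Methods: country-specific fracture probability under competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: country-specific fracture probability under competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(fracrisk)
```

## The problem

Fracture risk assessment tools report the 10-year probability of a major
osteoporotic fracture (MOF: hip, clinical spine, distal forearm or proximal
humerus) or of hip fracture alone. Building such a model for a new country
requires surprisingly little data — age- and sex-specific hip-fracture
incidence and national mortality — plus two structural assumptions: a
surrogate schedule turning hip incidence into MOF incidence, and a
competing-risk probability calculation that accounts for death before
fracture. `fracrisk` implements that construction pipeline end to end, for
epidemiologists assembling or auditing country-calibrated models where the
published engines are proprietary.

## The probability model

Let $\varphi(a)$ be the first-fracture hazard and $\mu(a)$ the death hazard
at age $a$, both per person-year. The probability of a first fracture within
horizon $H$ of age $a$ is

$$P(a, H) = \int_0^H \varphi(a+t)\,
  \exp\!\Big(-\!\int_0^t \big[\varphi(a+u) + \mu(a+u)\big]\,du\Big)\,dt,$$

the cumulative incidence of fracture in an illness–death model without
recovery. Death acts only as a competing risk: it can remove a person before
they fracture, so $P \le 1 - e^{-\int \varphi}$ always, and a population
with higher mortality can have *lower* fracture probability at identical
incidence — the mechanism behind published cases where the country with the
lower hip-fracture *incidence* has the higher *probability*, because its
mortality is lower.

Assumptions, stated explicitly:

* **Rate = hazard.** Incidence rates (per 100,000 person-years) are
  identified with hazards. This rare-event approximation is standard in
  fracture life-table work; the rates involved are well below 0.1/yr.
* **First fracture only.** No repeat events, no post-fracture mortality
  excess.
* **Risk factors act on the fracture hazard only.** No mortality
  coefficients are modelled, a documented divergence from fully calibrated
  engines.

## Numerical scheme

Hazards are piecewise constant on one-year age intervals. On each interval
with constant $\varphi_i$, $\mu_i$ and width $\Delta$, the integral has the
closed form
$$\frac{\varphi_i}{\varphi_i + \mu_i}\, S_i \big(1 -
e^{-(\varphi_i+\mu_i)\Delta}\big),$$
with survival $S_i$ carried between intervals. The accumulation is exact —
no quadrature tolerance, bit-for-bit reproducible. The test suite checks it
against an independent daily-step discrete-time oracle (midpoint quadrature
of the integrand with stepwise cumulative hazard) to far better than the
1e-5 requirement, and against constant-hazard closed forms to machine
precision.

Supplied rate tables are typically on 5-year age grids. Between grid points
the rate is interpolated **linearly on the log scale**, because fracture and
death rates grow near-exponentially with age (a Gompertz pattern); an
arithmetic interpolation would overshoot between widely spaced points. Zero
rates are floored at 1e-12 before taking logs and restored to exactly zero
wherever both bracketing rates are zero. Beyond the supplied range the rate
is clamped to the terminal values — a conservative, explicit choice given
that published tables rarely extend past age 90. Each one-year interval
takes the interpolated rate at its midpoint age.

## Surrogate MOF incidence

Where only hip fracture is measured, MOF incidence is estimated as
`hip_rate(a) * ratio(a)` with an age/sex ratio schedule (the "Swedish
pattern" assumption used by most country models with incomplete data).
Ratios are applied to **rates**, not probabilities — whether published
engines do likewise is not documented, so downstream comparisons are
structural, not numeric. Ratios interpolate linearly (they are slowly
varying and bounded; log scale adds nothing) and must be ≥ 1, since MOF
includes hip fracture; `validate_mof_dominance()` re-checks the implied
pointwise dominance, which propagates to `p_mof >= p_hip` downstream. No
published ratio values ship with the package: the bundled
`synthetic_mof_hip_ratios_female.csv` is a clearly labelled synthetic
example, and users should supply literature values.

## Risk-factor adjustment

Clinical risk factors enter as multiplicative relative risks on the
fracture hazard: prior fracture as a scalar per outcome (default 1.8),
femoral-neck BMD as `gradient^(t_ref - t)` per SD of T-score below an
age-indexed reference, and anything else through user-supplied `extra_rr`
multipliers. Multipliers compose exactly (`rr1` then `rr2` equals
`rr1 * rr2`), probability remains strictly increasing in each multiplier,
and saturation below 1 comes from the competing-risk integral itself, never
from clipping. The default gradients of risk (hip 3.7, MOF 1.6 per SD) are
literature-typical placeholders, **not** calibrated coefficients — the
original meta-analysis beta coefficients are proprietary and unprinted, so
this package deliberately exposes generic relative-risk machinery instead.
BMI has no built-in effect (published comparison grids fix it at 25 kg/m²);
the `extra_rr` hook exists for users with a BMI coefficient.

## Standardisation and comparison statistics

`age_standardise()` computes $\sum_i w_i\,p(\text{mid}_i)$ over a
user-supplied standard population (e.g. the UN world population from age
50), looking probabilities up at band midpoints rather than integrating
within bands — the source methods state only that summaries were
standardised, not the within-band scheme, so the simplest defensible
choice is used and verified by properties (scale invariance of weights,
result bounded by the curve's range). Cross-population statistics
(`age_ratio()`, `cross_population_spread()`, `column_range()`) operate on a
packaged grid of published 10-year probabilities stored exactly as printed,
including integer-rounded cells and a non-monotone old-age hip column.
Ratios round half-up to the stated decimals to reproduce printed figures
deterministically. Age-specific intervention thresholds follow the
fracture-threshold rule: the MOF probability of a same-age woman with a
prior fracture and no other risk factors.

## The synthetic world

The generator exists so every stage is testable without downloads. It
emulates:

* **Gompertz–Makeham age structure**: `rate(a) = base *
  exp(slope * (a - anchor)) + makeham * 1e5`, matching the near-exponential
  age increase of both fracture incidence and adult mortality.
* **Register-style counts**: Poisson events per age given person-year
  exposures, under a single global seed (determinism contract), with exact
  Garwood chi-square confidence intervals on the estimated rates.

Default parameters (female hip: base 13/100k at age 50, slope 0.080/yr;
female mortality: base 900/100k, slope 0.080/yr, Makeham 0.003/yr) were
chosen once to produce the realistic low-probability regime — female
10-year hip probabilities of roughly 0.2–1.4% across ages 50–90 under
high, steeply rising adult mortality. They are labelled synthetic and are
not estimates for any country. The initial analytic calibration ignored
mortality damping and was corrected during setup, before any test
asserted on the outputs.

What the generator does **not** emulate: hospital-register ascertainment
artefacts (case capture, duplicates), secular trends, cohort effects, or
within-age heterogeneity. A green test therefore establishes that the
pipeline recovers what it assumes — Poisson counts from smooth Gompertz
hazards — not that any real register meets those assumptions.

A steeper-mortality world (incidence slope 0.070/yr against mortality
slope 0.092/yr) is used to demonstrate the competing-risk mechanism: its
10-year hip probability rises to a peak near age 80–85 and then falls,
the same non-monotone tail visible in published low-incidence /
high-mortality columns.

## Design decisions on genuinely open points

* **Interval scheme**: exact per-interval accumulation over generic
  quadrature — exact, fast, reproducible.
* **Ages are exact ages**, not band midpoints; suppliers of banded data
  must pre-convert, because published tables give 5-year ages without band
  definitions.
* **Parameter-recovery criterion**: "slope within its standard error in
  ≥ 90% of replicates" is not attainable for any correctly specified
  estimator (±1 SE covers ~68%); the suite asserts 95%-CI coverage ≥ 90%
  instead and reports both coverages.
* **Published-grid reproduction is out of reach by design**: the
  underlying incidence rates and risk-factor coefficients are unprinted,
  and the published engine's integration scheme is undocumented, so
  acceptance rests on derived statistics of the packaged grid plus
  engine correctness by construction.

## Known limitations

* No site decomposition of MOF; only the aggregate.
* No time-attenuation of risk-factor effects and no BMD–risk-factor
  interaction terms.
* Mortality is never adjusted by risk factors.
* Clamped extrapolation understates hazards beyond the last supplied age
  if the true hazard keeps rising.
* Intervention thresholds take the prior-fracture relative risk as
  age-constant, whereas meta-analytic estimates decline with age.
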