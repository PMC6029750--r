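---
title: "Modeling the disease burden of CO2-induced zinc and iron decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the disease burden of CO2-induced zinc and iron decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Elevated atmospheric CO2 lowers the zinc and iron concentrations of C3 crops
(rice, wheat, legumes), which are the main dietary source of both nutrients in
the populations at highest risk of deficiency. `nutrisim` quantifies the
health consequences of that mechanism for one country at a time over
2015-2050, in four linked stages:

1. **Exposure.** CO2 rises linearly from 400 ppm toward 550 ppm; a mitigation
   scenario prevents a fraction of that rise. Each food category's zinc/iron
   concentration declines linearly from its 2015 value to
   `conc * (1 - decline_2050)` at the unmitigated endpoint, with the decline
   scaled proportionally to the realized CO2 rise (linear dose-response).
   Caloric consumption per category is held fixed: diets do not adapt.
   Per-capita supply is `sum(kcal / energy_density * concentration)` over
   categories (mg/capita/day).

2. **Deficiency.** Population intake in a year is a parametric distribution
   whose mean is that year's per-capita supply: normal with CV 25% (the
   default for both nutrients), or lognormal with CV 40% as the iron
   sensitivity alternative (moment-matched so arithmetic mean and CV equal
   the inputs). A person is deficient when intake falls below the
   population-weighted estimated average requirement (WtdEAR); population
   prevalence is the intake CDF at that cut-point (EAR cut-point method).

3. **Microsimulation.** Two samples of `n` individuals are initialized
   identically from the same seed. One arm experiences the nutrient declines;
   the counterfactual keeps 2015 concentrations. Zinc-deficient children
   under 5 face elevated relative risks of malaria, pneumonia, and diarrhea
   morbidity and mortality; every iron-deficient person-year accrues the iron
   deficiency anemia (IDA) disability weight and partitioned IDA mortality.
   Burden is counted in DALYs = YLL + YLD. The primary outcome is the
   exposed-minus-counterfactual difference, cumulative 2015-2050, per 1,000
   initial persons.

4. **Mitigation and uncertainty.** Six strategies (Paris-style climate
   mitigation preventing 47% of the rise, zinc and iron supplementation at
   80% coverage, three disease-control portfolios at 80% coverage, and their
   combination) are compared by the fraction of the attributable burden they
   avert. One-way (+/- 10%) and probabilistic Monte Carlo sensitivity
   analyses summarize input uncertainty with percentile credible intervals.

## Key parameters

| parameter | unit | default | note |
|---|---|---|---|
| CO2 endpoints | ppm | 400 (2015), 550 (2050) | linear path |
| Paris prevented fraction | — | 0.47 | scales declines by 0.53 |
| intake CV (zinc, iron) | — | 0.25 | normal family |
| iron alternative | — | lognormal, CV 0.40 | sensitivity switch |
| C3 crop declines at 550 ppm | fraction | 0.03-0.093 per category | zero for C4/animal foods |
| RR malaria/pneumonia/diarrhea | — | 1.56 / 1.52 / 1.28 | zinc-deficient under-5s |
| disability weights | — | 0.191 / 0.279 / 0.105 / 0.0312 | last is IDA |
| supplementation coverage | — | 0.80 | zinc: under-5s; iron: females over 5 |
| simulated persons per arm | — | 10,000 | desk-scale tests use less |

## Design decisions in the open parts of the design

Several pieces of the procedure are not fully pinned down by the published
description; the choices below are this package's own and are flagged as such.

**Annual time step, one death per year.** Intake, deficiency status, disease
person-time, and death are evaluated once per simulated year ("average annual
intake" is the natural unit). Disease deaths and background deaths are
mutually exclusive draws from one uniform per person-year, disease causes
first; this avoids double-counting at annual resolution.

**Common random numbers.** Each individual carries persistent intake
quantiles (`u_zinc`, `u_iron`) and persistent coverage-selection quantiles;
per-year event streams are derived deterministically from `(seed, year)`.
The two arms therefore differ *only* through the intake distributions, and
with zero declines (or 100% prevented rise) the attributable burden is
exactly zero, not merely zero in expectation. Coverage quantiles also make
covered sets nested in coverage, so averted fraction is monotone in coverage
essentially per-seed rather than only on average.

**Zinc-iron correlation.** `u_iron = u_zinc` by default (perfect rank
correlation): both intakes derive from the same diet, and the choice is
conservative for joint-deficiency overlap. `microsim_options(intake_correlation
= FALSE)` gives independence.

**Rate partition anchor.** Population-average (GBD-style) rates already
reflect existing deficiency. Rates are split into deficient/non-deficient
strata by `rate_nd = avg / (1 + f (rr - 1))`, with `f` held at the
counterfactual-arm 2015 analytic value: for the under-5 diseases
`f = P(under 5) * P(zinc deficient)` (age and intake rank are independent at
initialization), for IDA `f = P(iron deficient)`. Anchoring `f` keeps the
no-CO2 arm consistent with its epidemiological inputs; the exposed arm's
rates rise as more people cross the cut-point.

**IDA handling.** Iron deficiency is modeled as producing anemia directly:
every iron-deficient person-year accrues the IDA disability weight, and IDA
mortality defaults to `rr_ida = Inf`, i.e. all IDA deaths occur in the
deficient stratum (`rate = avg / f`). A finite `rr_ida` is available. The
`ida` prevalence field of the epidemiology table is carried in the schema for
reporting but is not used for YLD accrual, which follows deficiency itself.

**YLL.** Deaths contribute the remaining life expectancy of the decedent's
age band, from a per-profile table; no discounting or age-weighting (modern
GBD convention). The published description names no life table, so the
synthetic defaults (80/72/45/22 years for bands 0-4/5-14/15-49/50+) are
package choices.

**Demography.** Survivors age one year; births arrive at the crude birth
rate (deterministic rounding of `cbr * alive`) with attributes drawn from
shared per-year streams, keeping the cohort open and the arms aligned.

**Strategies.** Supplementation removes deficiency for covered individuals of
the target group (the simplest mechanism consistent with daily/weekly
administration under a cut-point framework); coverage selection is random
once per individual and fixed thereafter. Iron supplementation targets
*females over 5 years* (the methods wording; a figure caption in the source
says "women", a discrepancy we flag and resolve in favor of the methods
text). Disease-control portfolios multiply the target disease's prevalence
and mortality by `1 - coverage * efficacy` in both arms, so they avert only
the RR-mediated excess, never deficiency itself. Portfolio efficacies at
full coverage are **not** printed in the source; the defaults (0.5, with the
90%-coverage vaccine components of the pneumonia/diarrhea portfolios folded
in as a modest bump) are documented placeholders, and every headline
comparison in the test suite is asserted structurally (ordering, bounds),
never at printed percentages. Strategies act from 2015 at constant coverage.

**Probabilistic sensitivity.** Per draw, each listed input gets an
independent multiplier ~ Normal(1, 0.10) truncated positive and clamped to
natural bounds ([0,1] for fractions, [0,1) for declines, >= 1 for RRs); the
microsimulation seed is held fixed across draws so the summary isolates
input uncertainty (all-zero input SDs give a degenerate interval, a useful
self-check). The source's actual input distributions are in supplementary
material not available here; the module accepts any per-parameter relative
SDs in their place.

## The synthetic world

No real FAOSTAT/USDA/GBD extracts ship with the package. `make_world()`
generates country profiles from three archetypes whose single governing
parameter is the *margin to cut-point*: the number of intake SDs separating
the 2015 mean intake from the WtdEAR. Food concentrations are calibrated
after seeded jitter so the margin is exact, hence the analytic 2015
deficiency prevalence is `pnorm(-margin)` to machine precision. The margins
(0.47, 1.00, 1.79) bracket the published regional zinc-deficiency range:
32.0% (South-East-Asia-like) down to 3.7% (Europe-like). Diets range from
70% C3-staple energy (high burden) to 30% (low burden, more animal-source
food); disease intensity, under-5 fraction, and birth rates vary in the
same direction. The Nigeria fixture embeds the published example inputs
exactly (WtdEARs, prevalences, disability weights, RRs) and fills everything
else with documented synthetic values — it must not be read as real data.

What a green test establishes: the mechanics (calibration, partition
identity, CRN nulls, monotonicity, near-linearity of mitigation response)
behave as designed on data with the assumed statistical structure. What it
does not establish: agreement with the source study's global DALY estimates,
which require the full 137-country extracts and are out of scope here.

## Numerical choices

- Intake ties at exactly the cut-point count as non-deficient (strict `<`);
  a measure-zero event fixed for determinism.
- Normal-family quantiles are clamped at 0; the atom has mass
  `pnorm(-1/cv)` (~3e-5 at CV 25%) and those individuals are deficient for
  any positive cut-point. Concentrations are floored at 0 mg/100 g.
- Credible intervals are percentile intervals with linear interpolation
  between order statistics (quantile type 7).
- Derived seeds stay below 2^31; all stochastic entry points take an explicit
  seed and identical inputs reproduce bit-identical results.
- Profile CSVs are written with 17 significant digits so read/write
  round-trips are exact.

## Known limitations

- The attributable-burden estimate's YLL component is a small count of
  discrete deaths times large life expectancies; ratio summaries (averted
  fractions) need replicate seeds at desk scale to tame that noise.
- Burden is mildly superlinear in the decline (the normal CDF steepens below
  the mode and the cut-point z-score is convex in the decline), so the Paris
  averted fraction sits slightly below/near the prevented fraction (~0.46
  on the synthetic world) rather than exactly at it.
- No disease transmission dynamics, migration, seasonality, within-year
  episodes, bioavailability modeling beyond the WtdEAR inputs, or
  cost-effectiveness.
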