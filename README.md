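# nutrisim

Country-level microsimulation of the disease burden attributable to
carbon-dioxide-induced declines in the zinc and iron concentrations of crops,
2015–2050.

## The problem

Rising atmospheric CO2 (≈400 ppm in 2015, heading toward ≈550 ppm by 2050)
lowers the zinc and iron concentrations of C3 crops — rice, wheat, legumes —
which are the dominant dietary source of both nutrients precisely where
deficiency is already common. For epidemiologists and health-policy modelers,
the question is twofold: how much additional disease burden does that
mechanism create, and is climate mitigation or traditional public health
(supplementation, disease control) the better lever against it?

`nutrisim` implements the full chain as a tested, reusable R pipeline:

- **Exposure**: linear CO2 path; per-category crop concentrations declining
  linearly to `conc × (1 − decline₂₀₅₀)`, scaled by the prevented fraction of
  the CO2 rise; per-capita supply `Σ (kcal / energy density) × concentration`.
- **Deficiency**: EAR cut-point method — population prevalence is the intake
  CDF at the population-weighted estimated average requirement (WtdEAR);
  intake ~ Normal(μ, 0.25 μ), or lognormal (CV 40%) for iron in sensitivity
  analysis.
- **Microsimulation**: paired exposed/counterfactual samples with common
  random numbers; zinc-deficient under-5s carry relative risks (1.56/1.52/1.28)
  of malaria, pneumonia, and diarrhea morbidity and mortality via the
  average-preserving partition `rate_nd = avg / (1 + f(RR − 1))`; iron
  deficiency accrues the anemia disability weight. Outcome: attributable
  DALYs (YLL + YLD) per 1,000 persons, cumulative 2015–2050.
- **Mitigation**: six strategies — Paris-style climate mitigation (47% of the
  rise prevented), zinc/iron supplementation at 80% coverage, three disease
  control portfolios, and their combination — compared by averted fraction.
- **Sensitivity**: one-way ±10% tornado and probabilistic Monte Carlo with
  95% percentile credible intervals.
- **Synthetic data**: a generator of country profiles (archetypes calibrated
  so 2015 deficiency prevalence spans the 3.7%–32% regional range) replaces
  the external FAOSTAT/USDA/GBD extracts, so everything is testable offline.

## Worked example

```r
library(nutrisim)

profile <- make_country(archetype_spec("high_burden"), seed = 1)
dist <- build_intake_distribution(per_capita_supply(profile, "zinc", 2015),
                                  profile$intake_cv_zinc)
deficiency_prevalence(dist, profile$wtdear_zinc)
#> 2015 zinc deficiency prevalence: 0.319

res <- run_paired(profile, n = 10000, seed = 1)
res
#> Paired microsimulation burden (10000 individuals/arm)
#>   attributable DALYs 2015-2050: 973.54 (97.354 per 1,000 persons)
#>   counterfactual (no-CO2-rise) DALYs: 45961.57

strategies <- builtin_strategies()
paris <- run_paired(profile, strategy = strategies$paris, n = 10000, seed = 1)
averted_fraction(res$attributable_dalys, paris$attributable_dalys)
#> Paris averted fraction: 0.385
```

Reading the numbers: this high-burden archetype starts with 31.9% of the
population below the zinc cut-point (calibrated to Φ(−0.47)). Letting CO2
rise to 550 ppm adds ≈97 DALYs per 1,000 persons over 2015–2050 on top of a
much larger pre-existing deficiency burden (≈4,600 per 1,000); preventing
47% of the CO2 rise averts ≈39% of that increment in this single run — the
single-seed estimate is noisy because the YLL component is a handful of
discrete deaths, and averages to ≈0.46 over replicate seeds (see the
acceptance suite).

A full end-to-end run (burden per country and WHO region, mitigation
comparison, CSV outputs and a run log):

```r
run_pipeline(list(n_countries = 6, n = 2000, reps = 2, seed = 1),
             out_dir = "results")
```

or from a shell: `Rscript -e 'nutrisim::nutrisim_cli()' report --out results`.

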