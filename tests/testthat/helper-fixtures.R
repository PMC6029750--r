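# Shared fixtures, built in code at test time.

tiny_profile <- function(seed = 42, archetype = "high_burden") {
  make_country(archetype_spec(archetype), seed = seed)
}

# Profile with no modeled-disease burden at all (background mortality only).
zero_disease_profile <- function() {
  p <- tiny_profile()
  for (d in names(p$disease_epi)) {
    p$disease_epi[[d]]$prevalence_2015 <- 0
    p$disease_epi[[d]]$mortality_2015 <- 0
  }
  # No iron pathway either: push the iron cut-point to (numerically) zero
  # deficiency is impossible, so keep wtdear tiny instead.
  p$wtdear_iron <- 1e-6
  p$wtdear_zinc <- 1e-6
  validate_country_profile(p)
  p
}

# One-food profile for hand-computable supply arithmetic.
one_food_profile <- function(supply_kcal = 200, energy_density = 100,
                             zinc_conc = 2, iron_conc = 2,
                             zinc_decline = 0.1, iron_decline = 0.1) {
  p <- tiny_profile()
  p$foods <- data.frame(category = "c3_grain", supply_kcal = supply_kcal,
                        energy_density = energy_density,
                        zinc_conc_2015 = zinc_conc, iron_conc_2015 = iron_conc,
                        zinc_decline_2050 = zinc_decline,
                        iron_decline_2050 = iron_decline,
                        stringsAsFactors = FALSE)
  validate_country_profile(p)
  p
}

# Profile whose foods carry no decline at all (used for exact-null checks).
no_decline_profile <- function(seed = 42) {
  p <- tiny_profile(seed)
  p$foods$zinc_decline_2050 <- 0
  p$foods$iron_decline_2050 <- 0
  p
}

expect_profiles_equal <- function(a, b) {
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
}
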