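# Synthetic country-profile generator. Profiles carry everything one country
# needs for simulation: diet (food balance + composition + CO2 declines),
# demography, requirement cut-points, and disease epidemiology.

#' Construct and validate a country profile
#'
#' Low-level constructor; most users will call [make_country()],
#' [make_world()] or [nigeria_fixture()].
#'
#' @param country_id Short identifier string.
#' @param who_region One of AFR, AMR, SEAR, EUR, EMR, WPR.
#' @param population_2015 Number of persons represented.
#' @param demography data.frame with columns `age_band` (0-4, 5-14, 15-49,
#'   50+), `sex` (female/male), `weight` (population fraction, summing to 1),
#'   `background_mortality` (all-cause deaths/person/year excluding the modeled
#'   diseases) and `life_expectancy_remaining` (years, used for YLL).
#' @param crude_birth_rate Births/person/year.
#' @param foods data.frame with columns `category`, `supply_kcal`,
#'   `energy_density`, `zinc_conc_2015`, `iron_conc_2015`, `zinc_decline_2050`,
#'   `iron_decline_2050`.
#' @param wtdear_zinc,wtdear_iron Population-weighted estimated average
#'   requirements, mg/capita/day.
#' @param intake_cv_zinc,intake_cv_iron Coefficients of variation of the intake
#'   distributions.
#' @param iron_family Intake distribution family for iron (`"normal"` default;
#'   `"lognormal"` is the sensitivity alternative, conventionally with CV 0.40).
#' @param disease_epi Named list (malaria, pneumonia, diarrhea, ida) of lists
#'   with fields `prevalence_2015`, `prevalence_apc`, `mortality_2015`,
#'   `mortality_apc`, `disability_weight`, `rr_given_zinc_deficient`,
#'   `applies_to_under5_only`.
#' @return A validated object of class `country_profile`.
#' @export
country_profile <- function(country_id, who_region, population_2015,
                            demography, crude_birth_rate, foods,
                            wtdear_zinc, wtdear_iron,
                            intake_cv_zinc = 0.25, intake_cv_iron = 0.25,
                            iron_family = "normal", disease_epi) {
  profile <- structure(
    list(country_id = country_id, who_region = who_region,
         population_2015 = population_2015, demography = demography,
         crude_birth_rate = crude_birth_rate, foods = foods,
         wtdear_zinc = wtdear_zinc, wtdear_iron = wtdear_iron,
         intake_cv_zinc = intake_cv_zinc, intake_cv_iron = intake_cv_iron,
         iron_family = iron_family, disease_epi = disease_epi),
    class = "country_profile"
  )
  validate_country_profile(profile)
  profile
}

#' Validate a country profile
#'
#' Checks every structural invariant (weights sum to 1, positive cut-points,
#' CVs in (0,1), declines in \[0,1), one epidemiology entry per modeled
#' disease, ...) and stops with a message naming the offending field.
#'
#' @param profile A `country_profile`.
#' @return `profile`, invisibly.
#' @export
validate_country_profile <- function(profile) {
  if (!is.character(profile$country_id) || nchar(profile$country_id) == 0L) {
    fail_field("country_id", "must be a non-empty string")
  }
  if (!profile$who_region %in% WHO_REGIONS) {
    fail_field("who_region", paste("must be one of", paste(WHO_REGIONS, collapse = ", ")))
  }
  check_number(profile$population_2015, "population_2015", lower = 1)
  check_number(profile$crude_birth_rate, "crude_birth_rate", lower = 0)
  check_number(profile$wtdear_zinc, "wtdear_zinc", lower = 0, strict_lower = TRUE)
  check_number(profile$wtdear_iron, "wtdear_iron", lower = 0, strict_lower = TRUE)
  check_number(profile$intake_cv_zinc, "intake_cv_zinc", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(profile$intake_cv_iron, "intake_cv_iron", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!profile$iron_family %in% c("normal", "lognormal")) {
    fail_field("iron_family", "must be 'normal' or 'lognormal'")
  }

  dem <- profile$demography
  need <- c("age_band", "sex", "weight", "background_mortality",
            "life_expectancy_remaining")
  if (!is.data.frame(dem) || !all(need %in% names(dem))) {
    fail_field("demography", paste("must contain columns", paste(need, collapse = ", ")))
  }
  if (!all(dem$age_band %in% AGE_BANDS)) fail_field("demography$age_band", "unknown band")
  if (!all(dem$sex %in% c("female", "male"))) fail_field("demography$sex", "must be female/male")
  if (abs(sum(dem$weight) - 1) > 1e-9) fail_field("demography$weight", "must sum to 1 (tolerance 1e-9)")
  if (any(dem$weight < 0)) fail_field("demography$weight", "must be non-negative")
  if (any(dem$background_mortality < 0)) fail_field("demography$background_mortality", "must be non-negative")
  if (any(dem$life_expectancy_remaining < 0)) fail_field("demography$life_expectancy_remaining", "must be non-negative")
  if (nrow(unique(dem[, c("age_band", "sex")])) != nrow(dem)) {
    fail_field("demography", "duplicate (age_band, sex) cells")
  }

  foods <- profile$foods
  needf <- c("category", "supply_kcal", "energy_density", "zinc_conc_2015",
             "iron_conc_2015", "zinc_decline_2050", "iron_decline_2050")
  if (!is.data.frame(foods) || nrow(foods) == 0L || !all(needf %in% names(foods))) {
    fail_field("foods", paste("must be a non-empty data.frame with columns",
                              paste(needf, collapse = ", ")))
  }
  if (any(foods$supply_kcal < 0)) fail_field("foods$supply_kcal", "must be non-negative")
  if (any(foods$energy_density <= 0)) fail_field("foods$energy_density", "must be positive")
  if (any(foods$zinc_conc_2015 < 0) || any(foods$iron_conc_2015 < 0)) {
    fail_field("foods$*_conc_2015", "must be non-negative")
  }
  if (any(foods$zinc_decline_2050 < 0 | foods$zinc_decline_2050 >= 1) ||
      any(foods$iron_decline_2050 < 0 | foods$iron_decline_2050 >= 1)) {
    fail_field("foods$*_decline_2050", "must lie in [0, 1)")
  }

  epi <- profile$disease_epi
  if (!is.list(epi) || !setequal(names(epi), MODELED_DISEASES)) {
    fail_field("disease_epi", paste("must have exactly one entry per disease:",
                                    paste(MODELED_DISEASES, collapse = ", ")))
  }
  for (d in MODELED_DISEASES) {
    e <- epi[[d]]
    check_number(e$prevalence_2015, paste0("disease_epi$", d, "$prevalence_2015"),
                 lower = 0, upper = 1)
    check_number(e$mortality_2015, paste0("disease_epi$", d, "$mortality_2015"), lower = 0)
    check_number(e$disability_weight, paste0("disease_epi$", d, "$disability_weight"),
                 lower = 0, upper = 1)
    check_number(e$rr_given_zinc_deficient, paste0("disease_epi$", d, "$rr_given_zinc_deficient"),
                 lower = 1)
    check_number(e$prevalence_apc, paste0("disease_epi$", d, "$prevalence_apc"),
                 lower = -1, strict_lower = TRUE)
    check_number(e$mortality_apc, paste0("disease_epi$", d, "$mortality_apc"),
                 lower = -1, strict_lower = TRUE)
    if (!is.logical(e$applies_to_under5_only)) {
      fail_field(paste0("disease_epi$", d, "$applies_to_under5_only"), "must be logical")
    }
  }
  invisible(profile)
}

#' Archetype specification for synthetic countries
#'
#' Archetypes encode the regional contrast seen in real data: high-burden
#' settings have C3-staple-dominated diets with mean intakes only marginally
#' above the deficiency cut-point, while low-burden settings eat more
#' animal-source food and sit far above it. `margin_to_cutpoint` is the signed
#' number of intake SDs separating the 2015 mean intake from the WtdEAR, so the
#' analytic 2015 deficiency prevalence of a generated country is
#' `pnorm(-margin_to_cutpoint)` (normal family).
#'
#' @param name `"high_burden"`, `"middle"` or `"low_burden"`.
#' @param c3_energy_share Fraction of dietary energy from C3 staples, \[0, 1\].
#' @param margin_to_cutpoint Signed multiple of the intake SD.
#' @param disease_intensity Multiplier on default disease prevalence/mortality;
#'   must be positive.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name = c("high_burden", "middle", "low_burden"),
                           c3_energy_share = NULL, margin_to_cutpoint = NULL,
                           disease_intensity = NULL) {
  name <- match.arg(name)
  defaults <- list(
    # Margins chosen so baseline zinc deficiency brackets the printed regional
    # range: pnorm(-0.47) ~ 32% (South-East-Asia-like) down to
    # pnorm(-1.79) ~ 3.7% (Europe-like).
    high_burden = list(c3 = 0.70, margin = 0.47, intensity = 1.0),
    middle      = list(c3 = 0.50, margin = 1.00, intensity = 0.4),
    low_burden  = list(c3 = 0.30, margin = 1.79, intensity = 0.1)
  )[[name]]
  spec <- list(
    name = name,
    c3_energy_share = if (is.null(c3_energy_share)) defaults$c3 else c3_energy_share,
    margin_to_cutpoint = if (is.null(margin_to_cutpoint)) defaults$margin else margin_to_cutpoint,
    disease_intensity = if (is.null(disease_intensity)) defaults$intensity else disease_intensity
  )
  check_number(spec$c3_energy_share, "c3_energy_share", lower = 0, upper = 1)
  check_number(spec$disease_intensity, "disease_intensity", lower = 0, strict_lower = TRUE)
  check_number(spec$margin_to_cutpoint, "margin_to_cutpoint")
  structure(spec, class = "archetype_spec")
}

# ~10 aggregate food categories standing in for the ~100 FAOSTAT categories.
# kcal/100g and mg/100g are representative composition-table values; declines
# at the full 550 ppm rise are representative of free-air CO2 enrichment
# measurements on C3 crops (roughly 3%-10%); C4 maize and animal-source foods
# do not decline.
base_food_table <- function() {
  data.frame(
    category = c("c3_grain", "c3_legume", "maize", "roots", "bovine_meat",
                 "other_meat", "dairy", "fish", "vegetables", "other"),
    supply_kcal = 0,
    energy_density = c(364, 347, 365, 77, 250, 239, 61, 84, 34, 300),
    zinc_conc_2015 = c(2.9, 3.0, 2.2, 0.3, 6.3, 2.0, 0.4, 0.5, 0.3, 0.5),
    iron_conc_2015 = c(3.5, 6.2, 2.7, 0.8, 2.6, 1.3, 0.03, 0.3, 0.4, 1.0),
    zinc_decline_2050 = c(0.093, 0.062, 0, 0.030, 0, 0, 0, 0, 0.050, 0),
    iron_decline_2050 = c(0.051, 0.046, 0, 0.030, 0, 0, 0, 0, 0.050, 0),
    stringsAsFactors = FALSE
  )
}

# kcal allocation: C3 share split 70/30 between grain and legume; the
# remainder spread over the other categories with archetype-flavored weights.
allocate_kcal <- function(total_kcal, c3_share, animal_tilt, jitter) {
  non_c3 <- c(maize = 2, roots = 2, bovine_meat = 1 * animal_tilt,
              other_meat = 1 * animal_tilt, dairy = 1.5 * animal_tilt,
              fish = 0.5 * animal_tilt, vegetables = 1, other = 2)
  non_c3 <- non_c3 * jitter[seq_along(non_c3)]
  non_c3 <- non_c3 / sum(non_c3) * (1 - c3_share)
  shares <- c(c3_grain = 0.7 * c3_share, c3_legume = 0.3 * c3_share, non_c3)
  total_kcal * shares
}

default_demography <- function(under5_fraction) {
  # Band weights scale around the under-5 fraction; remaining mass split in
  # fixed proportions. Background mortality and remaining life expectancy are
  # synthetic, GBD-flavored values (not from any published table).
  rest <- 1 - under5_fraction
  band_w <- c(under5_fraction, rest * c(0.22, 0.55, 0.23) / 1.00)
  data.frame(
    age_band = rep(AGE_BANDS, each = 2),
    sex = rep(c("female", "male"), times = 4),
    weight = rep(band_w / 2, each = 2),
    background_mortality = rep(c(0.008, 0.001, 0.003, 0.030), each = 2),
    life_expectancy_remaining = rep(c(80, 72, 45, 22), each = 2),
    stringsAsFactors = FALSE
  )
}

default_disease_epi <- function(intensity, iron_def_prev) {
  # Prevalences, disability weights and RRs follow the published Nigeria
  # example; mortality levels and annual percent changes (APCs) are synthetic
  # defaults (GBD-flavored, declining trends).
  list(
    malaria = list(prevalence_2015 = 0.038 * intensity, prevalence_apc = -0.01,
                   mortality_2015 = 5e-4 * intensity, mortality_apc = -0.02,
                   disability_weight = 0.191, rr_given_zinc_deficient = 1.56,
                   applies_to_under5_only = TRUE),
    pneumonia = list(prevalence_2015 = 7.42e-4 * intensity, prevalence_apc = -0.01,
                     mortality_2015 = 6e-4 * intensity, mortality_apc = -0.02,
                     disability_weight = 0.279, rr_given_zinc_deficient = 1.52,
                     applies_to_under5_only = TRUE),
    diarrhea = list(prevalence_2015 = 0.055 * intensity, prevalence_apc = -0.01,
                    mortality_2015 = 5e-4 * intensity, mortality_apc = -0.02,
                    disability_weight = 0.105, rr_given_zinc_deficient = 1.28,
                    applies_to_under5_only = TRUE),
    ida = list(prevalence_2015 = min(1, iron_def_prev), prevalence_apc = 0,
               mortality_2015 = 5e-5 * intensity, mortality_apc = -0.02,
               disability_weight = 0.0312, rr_given_zinc_deficient = 1,
               applies_to_under5_only = FALSE)
  )
}

#' Generate one synthetic country profile
#'
#' Builds a country whose 2015 mean zinc (and iron) intake sits exactly
#' `margin_to_cutpoint` intake SDs above the WtdEAR: food zinc and iron
#' concentrations are scaled so the per-capita supply matches
#' `wtdear / (1 - margin * cv)`. With the normal intake family the analytic
#' 2015 deficiency prevalence is therefore `pnorm(-margin_to_cutpoint)`.
#' Small seeded jitter on the caloric allocation keeps countries distinct;
#' calibration happens after the jitter, so the margin is exact.
#'
#' @param spec An [archetype_spec()].
#' @param seed Non-negative integer; the result is deterministic in
#'   (`spec`, `seed`).
#' @param country_id,who_region Identifiers (defaults derived from the seed).
#' @return A validated `country_profile`.
#' @examples
#' p <- make_country(archetype_spec("high_burden"), seed = 1)
#' d <- build_intake_distribution(per_capita_supply(p, "zinc", 2015),
#'                                p$intake_cv_zinc)
#' deficiency_prevalence(d, p$wtdear_zinc)  # ~ pnorm(-0.47) = 0.319
#' @export
make_country <- function(spec, seed, country_id = sprintf("SYN%03d", seed %% 1000),
                         who_region = "AFR") {
  if (!inherits(spec, "archetype_spec")) spec <- do.call(archetype_spec, spec)
  check_number(seed, "seed", lower = 0)

  params <- list(
    high_burden = list(kcal = 2200, wz = 10.3, wf = 18.9, u5 = 0.16,
                       cbr = 0.035, tilt = 0.5, pop = 9e7),
    middle      = list(kcal = 2600, wz = 9.5, wf = 12.0, u5 = 0.10,
                       cbr = 0.020, tilt = 1.0, pop = 5e7),
    low_burden  = list(kcal = 3100, wz = 8.8, wf = 8.5, u5 = 0.05,
                       cbr = 0.011, tilt = 2.0, pop = 2e7)
  )[[spec$name]]

  foods <- base_food_table()
  jitter <- withr::with_seed(derive_seed(seed, 11), stats::runif(8, 0.9, 1.1))
  kcal <- allocate_kcal(params$kcal, spec$c3_energy_share, params$tilt, jitter)
  foods$supply_kcal <- as.numeric(kcal[foods$category])

  cv <- 0.25
  raw_z <- sum(foods$supply_kcal / foods$energy_density * foods$zinc_conc_2015)
  raw_f <- sum(foods$supply_kcal / foods$energy_density * foods$iron_conc_2015)
  if (spec$margin_to_cutpoint * cv >= 1) {
    fail_field("margin_to_cutpoint", "margin * cv must be < 1 for a positive target mean")
  }
  target_z <- params$wz / (1 - spec$margin_to_cutpoint * cv)
  target_f <- params$wf / (1 - spec$margin_to_cutpoint * cv)
  foods$zinc_conc_2015 <- foods$zinc_conc_2015 * target_z / raw_z
  foods$iron_conc_2015 <- foods$iron_conc_2015 * target_f / raw_f

  iron_def <- stats::pnorm(-spec$margin_to_cutpoint)
  country_profile(
    country_id = country_id, who_region = who_region,
    population_2015 = params$pop,
    demography = default_demography(params$u5),
    crude_birth_rate = params$cbr, foods = foods,
    wtdear_zinc = params$wz, wtdear_iron = params$wf,
    intake_cv_zinc = cv, intake_cv_iron = cv, iron_family = "normal",
    disease_epi = default_disease_epi(spec$disease_intensity, iron_def)
  )
}

#' Generate a synthetic world
#'
#' Countries cycle through the three archetypes and the six WHO regions, so
#' `make_world(6, seed)` covers every region with varied burden levels.
#'
#' @param n_countries Number of countries; at least 1.
#' @param seed Non-negative integer.
#' @return List of `country_profile` objects with unique ids.
#' @export
make_world <- function(n_countries, seed) {
  if (!is.numeric(n_countries) || n_countries < 1) {
    fail_field("n_countries", "must be at least 1")
  }
  archetypes <- c("high_burden", "middle", "low_burden")
  lapply(seq_len(n_countries), function(i) {
    make_country(
      archetype_spec(archetypes[(i - 1) %% 3 + 1]),
      seed = derive_seed(seed, 1000 + i),
      country_id = sprintf("SYN%03d", i),
      who_region = WHO_REGIONS[(i - 1) %% 6 + 1]
    )
  })
}

#' Nigeria example profile
#'
#' Embeds the published Nigeria example inputs exactly: WtdEARs 10.33 (zinc)
#' and 18.91 (iron) mg/capita/day; 2015 prevalences malaria 3.80e-2, pneumonia
#' 7.42e-4, diarrhea 5.50e-2; disability weights 0.191, 0.279, 0.105, 0.0312;
#' relative risks given zinc deficiency 1.56, 1.52, 1.28 (and 1 for iron
#' deficiency anemia, which follows the iron pathway). Every other field
#' (intake means, demography, mortality levels and trends, food composition)
#' is a documented synthetic stand-in, NOT a published value.
#'
#' @return A validated `country_profile`.
#' @export
nigeria_fixture <- function() {
  foods <- base_food_table()
  jitter <- rep(1, 8)
  kcal <- allocate_kcal(2200, 0.65, 0.5, jitter)
  foods$supply_kcal <- as.numeric(kcal[foods$category])

  # Synthetic margins: mean zinc intake 0.5 SD above the cut-point, iron 0.25.
  cv <- 0.25
  target_z <- 10.33 / (1 - 0.5 * cv)
  target_f <- 18.91 / (1 - 0.25 * cv)
  raw_z <- sum(foods$supply_kcal / foods$energy_density * foods$zinc_conc_2015)
  raw_f <- sum(foods$supply_kcal / foods$energy_density * foods$iron_conc_2015)
  foods$zinc_conc_2015 <- foods$zinc_conc_2015 * target_z / raw_z
  foods$iron_conc_2015 <- foods$iron_conc_2015 * target_f / raw_f

  epi <- default_disease_epi(1, stats::pnorm(-0.25))
  epi$malaria$prevalence_2015 <- 0.038
  epi$pneumonia$prevalence_2015 <- 7.42e-4
  epi$diarrhea$prevalence_2015 <- 0.055

  country_profile(
    country_id = "NGA", who_region = "AFR", population_2015 = 1.81e8,
    demography = default_demography(0.16), crude_birth_rate = 0.039,
    foods = foods, wtdear_zinc = 10.33, wtdear_iron = 18.91,
    intake_cv_zinc = cv, intake_cv_iron = cv, iron_family = "normal",
    disease_epi = epi
  )
}
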