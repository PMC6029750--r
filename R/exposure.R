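#' Atmospheric CO2 scenario
#'
#' Describes the atmospheric carbon dioxide trajectory between 2015 and 2050 as
#' a straight line from `ppm_2015` to the (possibly mitigated) 2050 endpoint.
#' Climate mitigation is expressed as the fraction of the 2015-2050 rise that
#' is prevented: 0 is business-as-usual (400 to 550 ppm, a 37.5% rise) and 0.47
#' corresponds to a Paris-Agreement-consistent pathway ending near 480 ppm.
#'
#' @param ppm_2015 CO2 concentration in 2015, ppm.
#' @param ppm_2050_unmitigated Unmitigated 2050 concentration, ppm.
#' @param fraction_rise_prevented Fraction of the 2015-2050 rise prevented,
#'   in \[0, 1\].
#' @return An object of class `co2_scenario`.
#' @examples
#' co2_at_year(co2_scenario(), 2050)                              # 550
#' co2_at_year(co2_scenario(fraction_rise_prevented = 0.47), 2050) # 479.5
#' @export
co2_scenario <- function(ppm_2015 = 400, ppm_2050_unmitigated = 550,
                         fraction_rise_prevented = 0) {
  check_number(ppm_2015, "ppm_2015", lower = 0)
  check_number(ppm_2050_unmitigated, "ppm_2050_unmitigated", lower = ppm_2015)
  check_number(fraction_rise_prevented, "fraction_rise_prevented", lower = 0, upper = 1)
  structure(
    list(ppm_2015 = ppm_2015,
         ppm_2050_unmitigated = ppm_2050_unmitigated,
         fraction_rise_prevented = fraction_rise_prevented),
    class = "co2_scenario"
  )
}

#' CO2 concentration at a given year
#'
#' Linear interpolation from the 2015 level to the scenario's 2050 endpoint,
#' `ppm_2015 + (1 - fraction_rise_prevented) * (ppm_2050_unmitigated - ppm_2015)`.
#'
#' @param scn A [co2_scenario()].
#' @param year Calendar year in \[2015, 2050\].
#' @return CO2 concentration in ppm.
#' @export
co2_at_year <- function(scn, year) {
  stopifnot(inherits(scn, "co2_scenario"))
  if (any(year < 2015 | year > 2050)) {
    stop("year must be within [2015, 2050]", call. = FALSE)
  }
  rise <- (1 - scn$fraction_rise_prevented) *
    (scn$ppm_2050_unmitigated - scn$ppm_2015)
  scn$ppm_2015 + rise * (year - 2015) / 35
}

#' Crop nutrient concentration under a CO2 scenario
#'
#' Concentrations decline linearly from their 2015 value to
#' `conc_2015 * (1 - decline_2050)` at the unmitigated 2050 endpoint; climate
#' mitigation scales the decline proportionally to the prevented CO2 rise
#' (linear dose-response). The result is floored at 0 mg/100 g.
#'
#' @param food A single row of a profile's `foods` table (list or one-row
#'   data.frame with `zinc_conc_2015`, `iron_conc_2015`, `zinc_decline_2050`,
#'   `iron_decline_2050`).
#' @param nutrient `"zinc"` or `"iron"`.
#' @param year Calendar year in \[2015, 2050\].
#' @param scn A [co2_scenario()].
#' @return Concentration in mg/100 g.
#' @export
nutrient_concentration <- function(food, nutrient, year, scn = co2_scenario()) {
  if (!nutrient %in% c("zinc", "iron")) {
    fail_field("nutrient", "must be 'zinc' or 'iron'")
  }
  if (any(year < 2015 | year > 2050)) {
    stop("year must be within [2015, 2050]", call. = FALSE)
  }
  conc0 <- if (nutrient == "zinc") food$zinc_conc_2015 else food$iron_conc_2015
  decline <- if (nutrient == "zinc") food$zinc_decline_2050 else food$iron_decline_2050
  effective <- decline * (1 - scn$fraction_rise_prevented)
  pmax(0, conc0 * (1 - effective * (year - 2015) / 35))
}

#' Per-capita nutrient supply from the food balance
#'
#' Sums over food categories: (kcal supplied / energy density) gives the mass
#' consumed in 100 g units, multiplied by the year- and scenario-specific
#' nutrient concentration. Caloric supply per category is held fixed across
#' years and scenarios (dietary patterns are assumed not to adjust).
#'
#' @param profile A `country_profile`.
#' @param nutrient `"zinc"` or `"iron"`.
#' @param year Calendar year in \[2015, 2050\].
#' @param scn A [co2_scenario()].
#' @return Supply in mg/capita/day.
#' @export
per_capita_supply <- function(profile, nutrient, year, scn = co2_scenario()) {
  foods <- profile$foods
  if (is.null(foods) || nrow(foods) == 0L) {
    fail_field("foods", "profile has an empty food list")
  }
  conc <- nutrient_concentration(foods, nutrient, year, scn)
  sum(foods$supply_kcal / foods$energy_density * conc)
}
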