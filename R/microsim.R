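# Paired-arm microsimulation. Two identical populations are initialized from
# the same seed; one is exposed to CO2-induced declines in crop zinc/iron
# concentrations while the counterfactual keeps 2015 concentrations. All event
# streams are derived deterministically from (seed, year), so with zero
# declines the arms are bit-identical and the attributable burden is exactly 0.

#' Project a rate forward by its annual percent change
#'
#' Secular trends continue exponentially:
#' `rate_2015 * (1 + apc)^(year - 2015)`, floored at 0.
#'
#' @param rate_2015 Rate in 2015, /year; non-negative.
#' @param apc Annual proportional change, signed; must exceed -1.
#' @param year Calendar year, at least 2015; vectorized.
#' @return Projected rate, /year.
#' @examples
#' project_rate(0.038, -0.02, 2050)  # 0.038 * 0.98^35
#' @export
project_rate <- function(rate_2015, apc, year) {
  check_number(rate_2015, "rate_2015", lower = 0)
  if (!is.numeric(apc) || apc <= -1) fail_field("apc", "must be > -1")
  if (any(year < 2015)) stop("year must be >= 2015", call. = FALSE)
  pmax(0, rate_2015 * (1 + apc)^(year - 2015))
}

#' Partition an average rate between deficient and non-deficient strata
#'
#' Population-level (GBD-style) rates already reflect the existing deficiency
#' burden. Given the deficient fraction `f` and relative risk `rr`, the strata
#' rates that reproduce the average exactly are
#' `rate_nondeficient = avg / (1 + f * (rr - 1))` and
#' `rate_deficient = rr * rate_nondeficient`.
#'
#' @param avg_rate Population-average rate, /year.
#' @param deficient_fraction Fraction of the rate's population that is
#'   deficient, \[0, 1\].
#' @param rr Relative risk for the deficient stratum; at least 1. `Inf` is
#'   allowed and assigns the whole rate to the deficient stratum
#'   (`rate_deficient = avg / f`, `rate_nondeficient = 0`).
#' @return Named numeric vector `c(nondeficient =, deficient =)`.
#' @examples
#' partition_rate_by_deficiency(0.10, 0.5, 1.5)  # c(0.08, 0.12)
#' @export
partition_rate_by_deficiency <- function(avg_rate, deficient_fraction, rr) {
  check_number(avg_rate, "avg_rate", lower = 0)
  check_number(deficient_fraction, "deficient_fraction", lower = 0, upper = 1)
  if (!is.numeric(rr) || rr < 1) fail_field("rr", "must be >= 1")
  if (is.infinite(rr)) {
    if (deficient_fraction > 0) {
      return(c(nondeficient = 0, deficient = avg_rate / deficient_fraction))
    }
    return(c(nondeficient = avg_rate, deficient = 0))
  }
  nd <- avg_rate / (1 + deficient_fraction * (rr - 1))
  c(nondeficient = nd, deficient = rr * nd)
}

#' Microsimulation options
#'
#' @param constant_prevalence Hold disease prevalence at its 2015 level
#'   (sensitivity scenario) instead of continuing its secular trend.
#' @param intake_correlation If `TRUE` (default) an individual's zinc and iron
#'   intake quantiles are equal (perfect rank correlation, both intakes derive
#'   from the same diet); if `FALSE` they are independent.
#' @param rr_ida Relative risk of iron-deficiency-anemia mortality for the
#'   iron-deficient stratum. The default `Inf` assigns all IDA mortality to
#'   the deficient stratum.
#' @return List of options.
#' @export
microsim_options <- function(constant_prevalence = FALSE,
                             intake_correlation = TRUE,
                             rr_ida = Inf) {
  if (!is.infinite(rr_ida)) check_number(rr_ida, "rr_ida", lower = 1)
  list(constant_prevalence = isTRUE(constant_prevalence),
       intake_correlation = isTRUE(intake_correlation),
       rr_ida = rr_ida)
}

age_range_in_band <- list(`0-4` = 0:4, `5-14` = 5:14, `15-49` = 15:49, `50+` = 50:84)

# Per-(band, sex) lookup matrices from the demography table.
demography_matrices <- function(dem) {
  bg <- le <- matrix(0, 4, 2, dimnames = list(AGE_BANDS, c("female", "male")))
  for (i in seq_len(nrow(dem))) {
    bg[dem$age_band[i], dem$sex[i]] <- dem$background_mortality[i]
    le[dem$age_band[i], dem$sex[i]] <- dem$life_expectancy_remaining[i]
  }
  list(bg = bg, le = le)
}

#' Initialize a simulated population
#'
#' Ages and sexes are drawn from the profile's demographic weights (uniform
#' within band); each individual receives persistent intake quantiles
#' (`u_zinc`, `u_iron`) and persistent coverage-selection quantiles used by
#' supplementation strategies. Deterministic for a fixed seed.
#'
#' @param profile A `country_profile`.
#' @param n Number of individuals; at least 1.
#' @param seed Non-negative integer.
#' @param options A [microsim_options()] list.
#' @return An object of class `population`.
#' @export
init_population <- function(profile, n, seed, options = microsim_options()) {
  if (!is.numeric(n) || n < 1) fail_field("n", "must be at least 1")
  validate_country_profile(profile)
  dem <- profile$demography
  pop <- withr::with_seed(derive_seed(seed, 1), {
    cell <- sample.int(nrow(dem), n, replace = TRUE, prob = dem$weight)
    band <- dem$age_band[cell]
    lo <- vapply(age_range_in_band[band], min, 0)
    hi <- vapply(age_range_in_band[band], max, 0)
    age <- floor(lo + stats::runif(n) * (hi - lo + 1))
    u_zinc <- stats::runif(n)
    u_iron_raw <- stats::runif(n)
    list(age = age,
         sex = dem$sex[cell],
         u_zinc = u_zinc,
         u_iron = if (options$intake_correlation) u_zinc else u_iron_raw,
         u_cov_zinc = stats::runif(n),
         u_cov_iron = stats::runif(n),
         alive = rep(TRUE, n))
  })
  pop$country_id <- profile$country_id
  pop$rng_seed <- seed
  pop$n_initial <- as.integer(n)
  pop$options <- options
  pop$lookup <- demography_matrices(dem)
  class(pop) <- "population"
  pop
}

in_target_group <- function(target, age, sex) {
  switch(target,
    children_under5 = age < 5,
    females_over5 = sex == "female" & age >= 5,
    whole_population = rep(TRUE, length(age)),
    not_applicable = rep(FALSE, length(age)),
    fail_field("target", "unknown target group")
  )
}

# Partition anchors: the counterfactual-arm 2015 analytic deficiency
# prevalences, held fixed over the simulation so population-average disease
# rates reproduce the GBD-style inputs. For the under-5 zinc pathway the
# anchor is P(under 5) * P(zinc deficient) (age and intake quantile are
# independent at initialization).
partition_anchors <- function(profile, options) {
  dz <- build_intake_distribution(per_capita_supply(profile, "zinc", 2015),
                                  profile$intake_cv_zinc, "normal")
  df <- build_intake_distribution(per_capita_supply(profile, "iron", 2015),
                                  profile$intake_cv_iron, profile$iron_family)
  f_z <- deficiency_prevalence(dz, profile$wtdear_zinc)
  f_f <- deficiency_prevalence(df, profile$wtdear_iron)
  w_u5 <- sum(profile$demography$weight[profile$demography$age_band == "0-4"])
  list(zinc = f_z, iron = f_f, zinc_under5 = f_z * w_u5)
}

#' Step a population through one simulated year
#'
#' For each living individual: (a) the year's scenario-specific intake
#' distributions are evaluated at the persistent quantiles and deficiency is
#' classified against the WtdEARs (supplementation may override deficiency for
#' covered members of the target group); (b) zinc-deficient under-5s face
#' RR-multiplied malaria/pneumonia/diarrhea rates via the partition identity,
#' everyone else the non-deficient rates; (c) iron-deficient person-years
#' accrue the IDA disability weight and face the partitioned IDA mortality;
#' (d) YLD for each infectious cause is the individual prevalence times the
#' disability weight; (e) at most one death per individual per year is drawn
#' (disease causes first, then background mortality), contributing YLL equal
#' to the remaining life expectancy of the age band; (f) survivors age one
#' year and births at the crude birth rate keep the cohort open.
#'
#' @param pop A [init_population()] object.
#' @param profile The `country_profile` being simulated.
#' @param year Calendar year in \[2015, 2050\].
#' @param scn The [co2_scenario()] governing this arm's nutrient declines.
#' @param strategy A `mitigation_strategy` (default none). The climate
#'   component of a strategy must already be reflected in `scn`; see
#'   [run_paired()].
#' @return List with elements `population` (stepped) and `slice` (per-cause
#'   yll/yld/deaths plus deficiency prevalences and person-years).
#' @export
simulate_year <- function(pop, profile, year, scn,
                          strategy = mitigation_strategy("none")) {
  stopifnot(inherits(pop, "population"))
  if (year < 2015 || year > 2050) stop("year must be within [2015, 2050]", call. = FALSE)
  eff <- strategy_effects(strategy)
  anchors <- partition_anchors(profile, pop$options)

  N <- length(pop$age)
  alive <- pop$alive
  n_alive <- sum(alive)

  # Shared per-year event streams (common random numbers across arms).
  year_seed <- derive_seed(pop$rng_seed, 200 + (year - 2015))
  streams <- withr::with_seed(year_seed, {
    cap <- as.integer(ceiling(0.08 * N) + 4L)
    list(u_death = stats::runif(N),
         birth = list(sex = stats::runif(cap), u_z = stats::runif(cap),
                      u_f = stats::runif(cap), cov_z = stats::runif(cap),
                      cov_f = stats::runif(cap)))
  })

  # Intake and deficiency under this arm's scenario.
  dist_z <- build_intake_distribution(per_capita_supply(profile, "zinc", year, scn),
                                      profile$intake_cv_zinc, "normal")
  dist_f <- build_intake_distribution(per_capita_supply(profile, "iron", year, scn),
                                      profile$intake_cv_iron, profile$iron_family)
  def_z <- is_deficient(pop$u_zinc, dist_z, profile$wtdear_zinc)
  def_f <- is_deficient(pop$u_iron, dist_f, profile$wtdear_iron)
  if (!is.null(eff$zinc)) {
    covered <- pop$u_cov_zinc < eff$zinc$coverage &
      in_target_group(eff$zinc$target, pop$age, pop$sex)
    def_z <- apply_supplementation(covered, def_z)
  }
  if (!is.null(eff$iron)) {
    covered <- pop$u_cov_iron < eff$iron$coverage &
      in_target_group(eff$iron$target, pop$age, pop$sex)
    def_f <- apply_supplementation(covered, def_f)
  }

  under5 <- pop$age < 5
  band <- age_band_index(pop$age)
  sex_col <- ifelse(pop$sex == "female", 1L, 2L)

  yll <- yld <- deaths <- stats::setNames(numeric(4), MODELED_DISEASES)
  p_mort <- matrix(0, N, 4, dimnames = list(NULL, MODELED_DISEASES))

  for (d in MODELED_DISEASES) {
    e <- profile$disease_epi[[d]]
    prev_apc <- if (pop$options$constant_prevalence) 0 else e$prevalence_apc
    prev_avg <- project_rate(e$prevalence_2015, prev_apc, year)
    mort_avg <- project_rate(e$mortality_2015, e$mortality_apc, year)
    ctrl <- eff$control[[d]]
    if (!is.null(ctrl)) {
      prev_avg <- apply_disease_control(prev_avg, ctrl, "prevalence")
      mort_avg <- apply_disease_control(mort_avg, ctrl, "mortality")
    }
    if (d == "ida") {
      # Iron pathway: every iron-deficient person-year accrues the IDA
      # disability weight; IDA mortality is partitioned over iron deficiency.
      part <- partition_rate_by_deficiency(mort_avg, anchors$iron, pop$options$rr_ida)
      p_mort[, d] <- part[["nondeficient"]] +
        (part[["deficient"]] - part[["nondeficient"]]) * def_f
      yld[d] <- sum(def_f[alive]) * e$disability_weight
    } else {
      f_anchor <- if (e$applies_to_under5_only) anchors$zinc_under5 else anchors$zinc
      rr <- e$rr_given_zinc_deficient
      in_rr_group <- if (e$applies_to_under5_only) def_z & under5 else def_z
      part_p <- partition_rate_by_deficiency(prev_avg, f_anchor, rr)
      part_m <- partition_rate_by_deficiency(mort_avg, f_anchor, rr)
      p_prev_i <- part_p[["nondeficient"]] +
        (part_p[["deficient"]] - part_p[["nondeficient"]]) * in_rr_group
      p_mort[, d] <- part_m[["nondeficient"]] +
        (part_m[["deficient"]] - part_m[["nondeficient"]]) * in_rr_group
      yld[d] <- sum(p_prev_i[alive]) * e$disability_weight
    }
  }

  # Mutually exclusive death draw: disease causes first, then background.
  p_bg <- pop$lookup$bg[cbind(band, sex_col)]
  cum <- 0
  died_any <- rep(FALSE, N)
  le_i <- pop$lookup$le[cbind(band, sex_col)]
  for (d in MODELED_DISEASES) {
    died_d <- alive & !died_any & streams$u_death >= cum &
      streams$u_death < cum + p_mort[, d]
    deaths[d] <- sum(died_d)
    yll[d] <- sum(le_i[died_d])
    died_any <- died_any | died_d
    cum <- cum + p_mort[, d]
  }
  died_bg <- alive & !died_any & streams$u_death >= cum &
    streams$u_death < pmin(1, cum + p_bg)
  died_any <- died_any | died_bg

  slice <- list(
    year = year,
    yll = yll, yld = yld, deaths = deaths,
    zinc_deficiency_prevalence = if (n_alive) mean(def_z[alive]) else NA_real_,
    iron_deficiency_prevalence = if (n_alive) mean(def_f[alive]) else NA_real_,
    person_years = n_alive,
    births = 0L
  )

  # Age survivors, retire the dead, append births.
  pop$alive <- alive & !died_any
  pop$age[pop$alive] <- pop$age[pop$alive] + 1L
  b <- min(length(streams$birth$sex),
           round(profile$crude_birth_rate * sum(pop$alive)))
  if (b > 0) {
    idx <- seq_len(b)
    u_z <- streams$birth$u_z[idx]
    pop$age <- c(pop$age, rep(0L, b))
    pop$sex <- c(pop$sex, ifelse(streams$birth$sex[idx] < 0.5, "female", "male"))
    pop$u_zinc <- c(pop$u_zinc, u_z)
    pop$u_iron <- c(pop$u_iron,
                    if (pop$options$intake_correlation) u_z else streams$birth$u_f[idx])
    pop$u_cov_zinc <- c(pop$u_cov_zinc, streams$birth$cov_z[idx])
    pop$u_cov_iron <- c(pop$u_cov_iron, streams$birth$cov_f[idx])
    pop$alive <- c(pop$alive, rep(TRUE, b))
    slice$births <- as.integer(b)
  }
  list(population = pop, slice = slice)
}

empty_burden_accumulator <- function(years) {
  ny <- length(years)
  m <- function() matrix(0, ny, 4, dimnames = list(years, MODELED_DISEASES))
  list(years = years, yll = m(), yld = m(), deaths = m(),
       zinc_deficiency_prevalence = stats::setNames(numeric(ny), years),
       iron_deficiency_prevalence = stats::setNames(numeric(ny), years),
       person_years = stats::setNames(numeric(ny), years))
}

# Run one arm over all years; returns a burden_result.
simulate_arm <- function(profile, scn, strategy, n, seed,
                         options = microsim_options(), years = SIM_YEARS) {
  pop <- init_population(profile, n, seed, options)
  acc <- empty_burden_accumulator(years)
  for (i in seq_along(years)) {
    step <- simulate_year(pop, profile, years[i], scn, strategy)
    pop <- step$population
    s <- step$slice
    acc$yll[i, ] <- s$yll
    acc$yld[i, ] <- s$yld
    acc$deaths[i, ] <- s$deaths
    acc$zinc_deficiency_prevalence[i] <- s$zinc_deficiency_prevalence
    acc$iron_deficiency_prevalence[i] <- s$iron_deficiency_prevalence
    acc$person_years[i] <- s$person_years
  }
  acc$n_initial <- pop$n_initial
  class(acc) <- "burden_result"
  acc
}

#' DALYs of a burden result
#'
#' DALYs are YLL + YLD, exactly, per cause and year.
#'
#' @param x A `burden_result` (or the attributable component of a
#'   [run_paired()] result).
#' @return Matrix of DALYs (year x cause).
#' @export
dalys <- function(x) {
  x$yll + x$yld
}

#' Run the paired exposed/counterfactual microsimulation
#'
#' Both arms are initialized from the same seed and stepped with identical
#' event streams (common random numbers). The exposed arm experiences the
#' scenario's nutrient declines (further scaled down if the strategy has a
#' climate component); the counterfactual arm keeps 2015 concentrations
#' throughout. The attributable burden is exposed minus counterfactual,
#' reported cumulatively over 2015-2050 and per 1,000 initial persons.
#'
#' @param profile A `country_profile`.
#' @param scn A [co2_scenario()]; default business-as-usual.
#' @param strategy A `mitigation_strategy`; default none.
#' @param n Individuals per arm.
#' @param seed Non-negative integer.
#' @param options A [microsim_options()] list.
#' @param years Years simulated (default 2015:2050).
#' @return An object of class `paired_burden` with components `exposed`,
#'   `counterfactual`, `attributable` (element-wise difference),
#'   `attributable_dalys` (cumulative) and `dalys_per_1000`.
#' @export
run_paired <- function(profile, scn = co2_scenario(),
                       strategy = mitigation_strategy("none"),
                       n = 10000, seed = 1,
                       options = microsim_options(), years = SIM_YEARS) {
  eff <- strategy_effects(strategy)
  # Compose the scenario's own mitigation with the strategy's climate
  # component (multiplicative on the remaining rise).
  frac <- 1 - (1 - scn$fraction_rise_prevented) * (1 - eff$fraction_rise_prevented)
  scn_exposed <- co2_scenario(scn$ppm_2015, scn$ppm_2050_unmitigated, frac)
  scn_counter <- co2_scenario(scn$ppm_2015, scn$ppm_2050_unmitigated, 1)

  exposed <- simulate_arm(profile, scn_exposed, strategy, n, seed, options, years)
  counter <- simulate_arm(profile, scn_counter, strategy, n, seed, options, years)

  attributable <- list(
    years = years,
    yll = exposed$yll - counter$yll,
    yld = exposed$yld - counter$yld,
    deaths = exposed$deaths - counter$deaths
  )
  res <- list(
    exposed = exposed, counterfactual = counter, attributable = attributable,
    attributable_dalys = sum(attributable$yll + attributable$yld),
    counterfactual_dalys = sum(dalys(counter)),
    n_initial = exposed$n_initial
  )
  res$dalys_per_1000 <- res$attributable_dalys / (res$n_initial / 1000)
  class(res) <- "paired_burden"
  res
}

#' @export
print.paired_burden <- function(x, ...) {
  cat("Paired microsimulation burden (", x$n_initial, " individuals/arm)\n", sep = "")
  cat(sprintf("  attributable DALYs 2015-2050: %.2f (%.3f per 1,000 persons)\n",
              x$attributable_dalys, x$dalys_per_1000))
  cat(sprintf("  counterfactual (no-CO2-rise) DALYs: %.2f\n", x$counterfactual_dalys))
  invisible(x)
}
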