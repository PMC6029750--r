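# CSV schemas, region aggregation, and the end-to-end pipeline.
#
# Input schemas (UTF-8, header row):
#   food_supply.csv: country_id, category, supply_kcal_per_capita_day
#   nutrients.csv:   category, kcal_per_100g, zinc_mg_per_100g, iron_mg_per_100g,
#                    zinc_decline_2050, iron_decline_2050
#   epi.csv:         country_id, disease, prevalence_2015, prevalence_apc,
#                    mortality_2015, mortality_apc, disability_weight, rr_zinc
#   demography.csv:  country_id, who_region, population_2015, age_band, sex,
#                    weight, background_mortality, life_expectancy_remaining,
#                    crude_birth_rate, wtdear_zinc, wtdear_iron

# Full-precision numeric formatting so CSV round-trips are exact.
fmt_num_cols <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  }
  df
}

write_schema_csv <- function(df, path) {
  utils::write.csv(fmt_num_cols(df), path, row.names = FALSE, quote = TRUE)
}

#' Write country profiles to the four-CSV directory schema
#'
#' @param profiles List of `country_profile` objects (a single profile is
#'   also accepted).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  if (inherits(profiles, "country_profile")) profiles <- list(profiles)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  food <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(country_id = p$country_id, category = p$foods$category,
               supply_kcal_per_capita_day = p$foods$supply_kcal,
               stringsAsFactors = FALSE)
  }))
  # Nutrient composition is per (country, category): synthetic calibration
  # makes concentrations country-specific, so country_id is kept as a key.
  nutrients <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(country_id = p$country_id, category = p$foods$category,
               kcal_per_100g = p$foods$energy_density,
               zinc_mg_per_100g = p$foods$zinc_conc_2015,
               iron_mg_per_100g = p$foods$iron_conc_2015,
               zinc_decline_2050 = p$foods$zinc_decline_2050,
               iron_decline_2050 = p$foods$iron_decline_2050,
               stringsAsFactors = FALSE)
  }))
  epi <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(MODELED_DISEASES, function(d) {
      e <- p$disease_epi[[d]]
      data.frame(country_id = p$country_id, disease = d,
                 prevalence_2015 = e$prevalence_2015, prevalence_apc = e$prevalence_apc,
                 mortality_2015 = e$mortality_2015, mortality_apc = e$mortality_apc,
                 disability_weight = e$disability_weight,
                 rr_zinc = e$rr_given_zinc_deficient,
                 stringsAsFactors = FALSE)
    }))
  }))
  demo <- do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(country_id = p$country_id, who_region = p$who_region,
                     population_2015 = p$population_2015, stringsAsFactors = FALSE),
          p$demography,
          data.frame(crude_birth_rate = p$crude_birth_rate,
                     wtdear_zinc = p$wtdear_zinc, wtdear_iron = p$wtdear_iron,
                     intake_cv_zinc = p$intake_cv_zinc,
                     intake_cv_iron = p$intake_cv_iron,
                     iron_family = p$iron_family, stringsAsFactors = FALSE))
  }))

  write_schema_csv(food, file.path(dir, "food_supply.csv"))
  write_schema_csv(nutrients, file.path(dir, "nutrients.csv"))
  write_schema_csv(epi, file.path(dir, "epi.csv"))
  write_schema_csv(demo, file.path(dir, "demography.csv"))
  invisible(dir)
}

read_schema_csv <- function(dir, name, required) {
  path <- file.path(dir, name)
  if (!file.exists(path)) stop(sprintf("missing input file '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", name, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in required) {
    bad <- which(is.na(df[[nm]]))
    if (length(bad)) {
      stop(sprintf("%s: missing value in column '%s', row %d", name, nm, bad[1]),
           call. = FALSE)
    }
  }
  df
}

#' Read country profiles from the four-CSV directory schema
#'
#' Joins the four files on `country_id` (and food `category`), validates every
#' profile, and fails hard with a message naming the file and row for missing
#' or invalid cells.
#'
#' @param dir Directory containing `food_supply.csv`, `nutrients.csv`,
#'   `epi.csv`, `demography.csv`.
#' @return List of validated `country_profile` objects.
#' @export
read_profiles <- function(dir) {
  food <- read_schema_csv(dir, "food_supply.csv",
                          c("country_id", "category", "supply_kcal_per_capita_day"))
  nutrients <- read_schema_csv(dir, "nutrients.csv",
                               c("country_id", "category", "kcal_per_100g",
                                 "zinc_mg_per_100g", "iron_mg_per_100g",
                                 "zinc_decline_2050", "iron_decline_2050"))
  epi <- read_schema_csv(dir, "epi.csv",
                         c("country_id", "disease", "prevalence_2015", "prevalence_apc",
                           "mortality_2015", "mortality_apc", "disability_weight",
                           "rr_zinc"))
  demo <- read_schema_csv(dir, "demography.csv",
                          c("country_id", "who_region", "population_2015", "age_band",
                            "sex", "weight", "background_mortality",
                            "life_expectancy_remaining", "crude_birth_rate",
                            "wtdear_zinc", "wtdear_iron"))

  bad <- which(food$supply_kcal_per_capita_day < 0)
  if (length(bad)) {
    stop(sprintf("food_supply.csv: negative kcal supply in row %d (country %s, category %s)",
                 bad[1], food$country_id[bad[1]], food$category[bad[1]]), call. = FALSE)
  }

  lapply(unique(demo$country_id), function(cid) {
    d <- demo[demo$country_id == cid, , drop = FALSE]
    f <- food[food$country_id == cid, , drop = FALSE]
    nu <- nutrients[nutrients$country_id == cid, , drop = FALSE]
    e <- epi[epi$country_id == cid, , drop = FALSE]
    if (nrow(f) == 0) stop(sprintf("food_supply.csv: no rows for country %s", cid), call. = FALSE)
    j <- match(f$category, nu$category)
    if (anyNA(j)) {
      stop(sprintf("nutrients.csv: category '%s' of country %s has no composition row",
                   f$category[which(is.na(j))[1]], cid), call. = FALSE)
    }
    foods <- data.frame(category = f$category,
                        supply_kcal = f$supply_kcal_per_capita_day,
                        energy_density = nu$kcal_per_100g[j],
                        zinc_conc_2015 = nu$zinc_mg_per_100g[j],
                        iron_conc_2015 = nu$iron_mg_per_100g[j],
                        zinc_decline_2050 = nu$zinc_decline_2050[j],
                        iron_decline_2050 = nu$iron_decline_2050[j],
                        stringsAsFactors = FALSE)
    disease_epi <- stats::setNames(lapply(MODELED_DISEASES, function(dz) {
      r <- e[e$disease == dz, , drop = FALSE]
      if (nrow(r) != 1) {
        stop(sprintf("epi.csv: country %s needs exactly one row for disease '%s'", cid, dz),
             call. = FALSE)
      }
      list(prevalence_2015 = r$prevalence_2015, prevalence_apc = r$prevalence_apc,
           mortality_2015 = r$mortality_2015, mortality_apc = r$mortality_apc,
           disability_weight = r$disability_weight,
           rr_given_zinc_deficient = r$rr_zinc,
           applies_to_under5_only = dz != "ida")
    }), MODELED_DISEASES)
    country_profile(
      country_id = cid, who_region = d$who_region[1],
      population_2015 = d$population_2015[1],
      demography = data.frame(age_band = d$age_band, sex = d$sex, weight = d$weight,
                              background_mortality = d$background_mortality,
                              life_expectancy_remaining = d$life_expectancy_remaining,
                              stringsAsFactors = FALSE),
      crude_birth_rate = d$crude_birth_rate[1], foods = foods,
      wtdear_zinc = d$wtdear_zinc[1], wtdear_iron = d$wtdear_iron[1],
      intake_cv_zinc = if ("intake_cv_zinc" %in% names(d)) d$intake_cv_zinc[1] else 0.25,
      intake_cv_iron = if ("intake_cv_iron" %in% names(d)) d$intake_cv_iron[1] else 0.25,
      iron_family = if ("iron_family" %in% names(d)) d$iron_family[1] else "normal",
      disease_epi = disease_epi
    )
  })
}

#' Aggregate country burdens to WHO regions and the globe
#'
#' DALYs are summed exactly within regions; per-1,000 metrics are recomputed
#' on the summed simulated populations (so two identical countries double the
#' region's DALYs but leave its per-1,000 burden unchanged). A `GLOBAL` row is
#' appended.
#'
#' @param results data.frame with columns `country_id`, `who_region`,
#'   `population` (initial simulated persons), `attributable_dalys`,
#'   `baseline_dalys` (counterfactual no-CO2-rise burden).
#' @return data.frame with one row per region plus `GLOBAL`, columns
#'   `who_region`, `population`, `cumulative_dalys`, `dalys_per_1000`,
#'   `baseline_dalys`, `baseline_dalys_per_1000`.
#' @export
aggregate_regions <- function(results) {
  need <- c("country_id", "who_region", "population", "attributable_dalys",
            "baseline_dalys")
  if (!all(need %in% names(results))) {
    fail_field("results", paste("must contain columns", paste(need, collapse = ", ")))
  }
  if (any(is.na(results$who_region)) || !all(results$who_region %in% WHO_REGIONS)) {
    fail_field("who_region", "every country must carry a valid WHO region label")
  }
  agg_one <- function(df, label) {
    data.frame(who_region = label,
               population = sum(df$population),
               cumulative_dalys = sum(df$attributable_dalys),
               dalys_per_1000 = sum(df$attributable_dalys) / (sum(df$population) / 1000),
               baseline_dalys = sum(df$baseline_dalys),
               baseline_dalys_per_1000 = sum(df$baseline_dalys) / (sum(df$population) / 1000),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(split(results, results$who_region), agg_one,
                 label = NA_character_)
  for (r in names(rows)) rows[[r]]$who_region <- r
  out <- do.call(rbind, c(rows, list(agg_one(results, "GLOBAL"))))
  rownames(out) <- NULL
  out
}

#' Parse a key-value configuration file
#'
#' Lines of `key = value`; `#` starts a comment. Logical values `true/false`,
#' numerics parsed as numbers, everything else kept as strings.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop(sprintf("config: cannot parse line '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  out
}

default_pipeline_config <- function() {
  list(n_countries = 6, n = 2000, reps = 2, seed = 1, scenario = "baseline",
       iron_lognormal = FALSE, constant_prevalence = FALSE,
       intake_correlation = TRUE, mitigation = TRUE, sensitivity = FALSE,
       profiles_dir = "")
}

config_options <- function(config) {
  microsim_options(constant_prevalence = isTRUE(config$constant_prevalence),
                   intake_correlation = !isFALSE(config$intake_correlation))
}

apply_iron_lognormal <- function(profile) {
  profile$iron_family <- "lognormal"
  profile$intake_cv_iron <- 0.40
  validate_country_profile(profile)
}

#' Run the full pipeline
#'
#' Generates (or reads) country profiles, runs the paired burden
#' microsimulation per country, aggregates to WHO regions, optionally runs the
#' mitigation comparison and a compact sensitivity analysis, and writes
#' `burden_by_country.csv`, `burden_by_region.csv`, `mitigation.csv`,
#' `sensitivity.csv` and a `run_log.txt` recording the effective
#' configuration. Deterministic for a fixed config.
#'
#' @param config Named list (see `default_pipeline_config()` internals) or a
#'   path to a key-value config file. Keys: `n_countries`, `n`, `reps`,
#'   `seed`, `scenario` ("baseline" or "paris"), `iron_lognormal`,
#'   `constant_prevalence`, `intake_correlation`, `mitigation`, `sensitivity`,
#'   `profiles_dir` (read instead of generating when non-empty).
#' @param out_dir Output directory.
#' @return Invisible list with `burden`, `regions`, `mitigation`,
#'   `sensitivity` components.
#' @export
run_pipeline <- function(config = list(), out_dir = "results") {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  profiles <- if (nzchar(cfg$profiles_dir)) {
    read_profiles(cfg$profiles_dir)
  } else {
    make_world(cfg$n_countries, cfg$seed)
  }
  if (isTRUE(cfg$iron_lognormal)) profiles <- lapply(profiles, apply_iron_lognormal)
  options <- config_options(cfg)
  scn <- if (identical(cfg$scenario, "paris")) {
    co2_scenario(fraction_rise_prevented = 0.47)
  } else co2_scenario()
  strategies <- builtin_strategies()

  run_mean <- function(profile, strategy) {
    runs <- lapply(seq_len(cfg$reps), function(r) {
      run_paired(profile, scn, strategy, n = cfg$n,
                 seed = derive_seed(cfg$seed, 500 + r), options = options)
    })
    list(attributable = mean(vapply(runs, function(x) x$attributable_dalys, numeric(1))),
         per_1000 = mean(vapply(runs, function(x) x$dalys_per_1000, numeric(1))),
         baseline = mean(vapply(runs, function(x) x$counterfactual_dalys, numeric(1))))
  }

  burden <- do.call(rbind, lapply(profiles, function(p) {
    r <- run_mean(p, strategies$none)
    data.frame(country_id = p$country_id, who_region = p$who_region,
               population = cfg$n, attributable_dalys = r$attributable,
               dalys_per_1000 = r$per_1000, baseline_dalys = r$baseline,
               stringsAsFactors = FALSE)
  }))
  regions <- aggregate_regions(burden)

  mitigation <- NULL
  if (isTRUE(cfg$mitigation)) {
    mitigation <- do.call(rbind, lapply(profiles, function(p) {
      base <- run_mean(p, strategies$none)
      do.call(rbind, lapply(setdiff(names(strategies), "none"), function(s) {
        with_s <- run_mean(p, strategies[[s]])
        data.frame(country_id = p$country_id, who_region = p$who_region,
                   strategy = s,
                   averted_fraction = averted_fraction(base$attributable,
                                                       with_s$attributable),
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  sens <- NULL
  if (isTRUE(cfg$sensitivity)) {
    sens <- one_way(profiles[[1]], scn, strategies$none,
                    n = min(cfg$n, 2000), reps = cfg$reps, seed = cfg$seed,
                    options = options)
  }

  write_schema_csv(burden, file.path(out_dir, "burden_by_country.csv"))
  write_schema_csv(regions, file.path(out_dir, "burden_by_region.csv"))
  if (!is.null(mitigation)) write_schema_csv(mitigation, file.path(out_dir, "mitigation.csv"))
  if (!is.null(sens)) write_schema_csv(sens, file.path(out_dir, "sensitivity.csv"))

  log_lines <- c(sprintf("nutrisim %s", as.character(utils::packageVersion("nutrisim"))),
                 sprintf("R %s", getRversion()),
                 "effective config:",
                 vapply(names(cfg), function(k) sprintf("  %s = %s", k, cfg[[k]]),
                        character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(burden = burden, regions = regions, mitigation = mitigation,
                 sensitivity = sens, config = cfg))
}
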