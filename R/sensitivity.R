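# One-way (+/- 10%) and probabilistic sensitivity analysis.

# Dotted parameter paths into a country_profile:
#   "wtdear_iron", "intake_cv_zinc", "crude_birth_rate",
#   "disease_epi.malaria.prevalence_2015",
#   "foods.c3_grain.supply_kcal", "demography.0-4.female.weight" (read-only
#   weights are renormalized after perturbation).

#' Read a profile parameter by dotted path
#' @param profile A `country_profile`.
#' @param path Dotted parameter path (see Details in [perturb_profile()]).
#' @return Numeric value.
#' @export
get_param <- function(profile, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- switch(p[1],
    disease_epi = if (length(p) == 3) profile$disease_epi[[p[2]]][[p[3]]],
    foods = if (length(p) == 3) {
      i <- match(p[2], profile$foods$category)
      if (!is.na(i)) profile$foods[[p[3]]][i]
    },
    demography = if (length(p) == 4) {
      i <- which(profile$demography$age_band == p[2] & profile$demography$sex == p[3])
      if (length(i) == 1) profile$demography[[p[4]]][i]
    },
    if (length(p) == 1) profile[[p[1]]]
  )
  if (is.null(out) || !is.numeric(out)) {
    fail_field("parameter_path", paste0("'", path, "' does not resolve to a numeric parameter"))
  }
  out
}

# Natural-bound clamp by field name; fractions stay in [0,1], declines in
# [0,1), CVs in (0,1). Values are clamped, not rejected (the +/-10% convention
# can push bounded inputs past their natural bounds).
clamp_param <- function(path, value) {
  leaf <- utils::tail(strsplit(path, ".", fixed = TRUE)[[1]], 1)
  if (grepl("^(prevalence_2015|disability_weight|weight)$", leaf)) {
    return(min(1, max(0, value)))
  }
  if (grepl("_decline_2050$", leaf)) return(min(1 - 1e-9, max(0, value)))
  if (grepl("^intake_cv", leaf)) return(min(1 - 1e-9, max(1e-9, value)))
  if (grepl("^rr_", leaf)) return(max(1, value))
  max(0, value)
}

#' Perturb one profile parameter multiplicatively
#'
#' Returns a copy of the profile with the parameter at `path` multiplied by
#' `multiplier`, clamped to its natural bounds. Demography weights are
#' renormalized to sum to 1 after perturbation.
#'
#' @param profile A `country_profile`.
#' @param path Dotted parameter path.
#' @param multiplier Positive multiplier.
#' @return A validated perturbed `country_profile`.
#' @export
perturb_profile <- function(profile, path, multiplier) {
  check_number(multiplier, "multiplier", lower = 0, strict_lower = TRUE)
  value <- clamp_param(path, get_param(profile, path) * multiplier)
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (p[1] == "disease_epi") {
    profile$disease_epi[[p[2]]][[p[3]]] <- value
  } else if (p[1] == "foods") {
    i <- match(p[2], profile$foods$category)
    profile$foods[[p[3]]][i] <- value
  } else if (p[1] == "demography") {
    i <- which(profile$demography$age_band == p[2] & profile$demography$sex == p[3])
    profile$demography[[p[4]]][i] <- value
    if (p[4] == "weight") {
      profile$demography$weight <- profile$demography$weight / sum(profile$demography$weight)
    }
  } else {
    profile[[p[1]]] <- value
  }
  validate_country_profile(profile)
  profile
}

default_sensitivity_parameters <- function(profile) {
  c("wtdear_zinc", "wtdear_iron", "intake_cv_zinc", "intake_cv_iron",
    "disease_epi.malaria.prevalence_2015", "disease_epi.malaria.mortality_2015",
    "disease_epi.pneumonia.prevalence_2015", "disease_epi.pneumonia.mortality_2015",
    "disease_epi.diarrhea.prevalence_2015", "disease_epi.diarrhea.mortality_2015",
    "disease_epi.ida.mortality_2015", "disease_epi.ida.disability_weight",
    "disease_epi.malaria.disability_weight", "disease_epi.pneumonia.disability_weight",
    "disease_epi.diarrhea.disability_weight")
}

#' One-way sensitivity analysis
#'
#' Each parameter is perturbed alone by x0.9 and x1.1 (values clamped to
#' natural bounds); the outcome is the mean attributable DALYs per 1,000 over
#' `reps` paired runs. Common random numbers are reused within each low/high
#' pair, so a parameter with no causal path to the outcome yields exactly zero
#' spread. Results are sorted by |high - low| descending (tornado order).
#'
#' @param profile A `country_profile`.
#' @param scn A [co2_scenario()].
#' @param strategy A `mitigation_strategy`.
#' @param parameters Character vector of dotted paths; defaults to the main
#'   model inputs.
#' @param n Individuals per arm per run.
#' @param reps Replicate runs per perturbation.
#' @param seed Non-negative integer.
#' @param options A [microsim_options()] list.
#' @return data.frame with columns `parameter`, `low`, `high`, `spread`,
#'   sorted by spread.
#' @export
one_way <- function(profile, scn = co2_scenario(),
                    strategy = mitigation_strategy("none"),
                    parameters = default_sensitivity_parameters(profile),
                    n = 2000, reps = 3, seed = 1,
                    options = microsim_options()) {
  if (reps < 1) fail_field("reps", "must be at least 1")
  outcome <- function(prof) {
    mean(vapply(seq_len(reps), function(r) {
      run_paired(prof, scn, strategy, n = n, seed = derive_seed(seed, 300 + r),
                 options = options)$dalys_per_1000
    }, numeric(1)))
  }
  rows <- lapply(parameters, function(path) {
    data.frame(parameter = path,
               low = outcome(perturb_profile(profile, path, 0.9)),
               high = outcome(perturb_profile(profile, path, 1.1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$high - out$low)
  out[order(-out$spread), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Per draw, every listed parameter receives an independent multiplier sampled
#' from Normal(1, `rel_sd`) truncated to positive values (values clamped to
#' natural bounds on assignment), the model is run once, and the outcome is
#' recorded. The microsimulation seed is held fixed across draws so that the
#' summary isolates input uncertainty: with all input SDs at zero the summary
#' is degenerate (`ci_low == ci_high == mean`).
#'
#' @param profile A `country_profile`.
#' @param scn A [co2_scenario()].
#' @param strategy A `mitigation_strategy`.
#' @param parameters Dotted paths sampled per draw.
#' @param rel_sd Relative SD of the input multipliers (default 0.10). May be a
#'   named vector keyed by parameter path (unnamed scalar recycled).
#' @param n_draws Number of Monte Carlo draws; at least 2.
#' @param n Individuals per arm per run.
#' @param seed Non-negative integer.
#' @param options A [microsim_options()] list.
#' @param outcome_fun Function mapping a `paired_burden` to a scalar outcome;
#'   defaults to attributable DALYs per 1,000.
#' @return List of class `uncertainty_summary`: `mean`, `sd`, `ci_low`,
#'   `ci_high` (2.5th/97.5th percentiles), `n_draws`, `draws`.
#' @export
probabilistic <- function(profile, scn = co2_scenario(),
                          strategy = mitigation_strategy("none"),
                          parameters = default_sensitivity_parameters(profile),
                          rel_sd = 0.10, n_draws = 100, n = 2000, seed = 1,
                          options = microsim_options(),
                          outcome_fun = function(pb) pb$dalys_per_1000) {
  if (n_draws < 2) fail_field("n_draws", "must be at least 2")
  if (any(rel_sd < 0)) fail_field("rel_sd", "must be non-negative")
  sds <- if (length(rel_sd) == 1L) stats::setNames(rep(rel_sd, length(parameters)), parameters)
         else rel_sd[parameters]
  if (anyNA(sds)) fail_field("rel_sd", "named vector must cover every parameter")
  model_seed <- derive_seed(seed, 9)
  draws <- vapply(seq_len(n_draws), function(d) {
    mult <- withr::with_seed(derive_seed(seed, 400 + d), {
      m <- stats::rnorm(length(parameters), 1, sds)
      pmax(m, 1e-6)
    })
    prof <- profile
    for (i in seq_along(parameters)) {
      prof <- perturb_profile(prof, parameters[i], mult[i])
    }
    outcome_fun(run_paired(prof, scn, strategy, n = n, seed = model_seed,
                           options = options))
  }, numeric(1))
  ci <- credible_interval(draws, 0.95)
  structure(list(mean = mean(draws), sd = stats::sd(draws),
                 ci_low = ci[1], ci_high = ci[2],
                 n_draws = n_draws, draws = draws),
            class = "uncertainty_summary")
}

#' Empirical credible interval
#'
#' Percentile interval at `(1-level)/2` and `1-(1-level)/2` with linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param draws Numeric vector of at least 2 outcomes.
#' @param level Interval mass, in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' credible_interval(1:100, 0.95)  # c(3.475, 97.525)
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2) fail_field("draws", "need at least 2 draws")
  check_number(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  alpha <- (1 - level) / 2
  unname(stats::quantile(draws, c(alpha, 1 - alpha), type = 7))
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary over %d draws: mean %.4f (sd %.4f), 95%% CrI [%.4f, %.4f]\n",
              x$n_draws, x$mean, x$sd, x$ci_low, x$ci_high))
  invisible(x)
}
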