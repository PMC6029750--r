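#' Parametric nutrient intake distribution
#'
#' Yearly average intake across a population is modeled parametrically: normal
#' with SD = cv * mean (quantiles clamped at 0), or lognormal with parameters
#' moment-matched so the arithmetic mean and coefficient of variation equal the
#' inputs (`sigma^2 = log(1 + cv^2)`, `mu = log(mean) - sigma^2 / 2`).
#'
#' @param mean Arithmetic mean intake, mg/day; must be positive.
#' @param cv Coefficient of variation (SD/mean), in (0, 1).
#' @param family `"normal"` or `"lognormal"`.
#' @return An object of class `intake_distribution`.
#' @examples
#' d <- build_intake_distribution(10, 0.25, "normal")
#' intake_quantile(d, 0.5)  # 10
#' @export
build_intake_distribution <- function(mean, cv, family = c("normal", "lognormal")) {
  check_number(mean, "mean", lower = 0, strict_lower = TRUE)
  check_number(cv, "cv", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (!is.character(family) || !all(family %in% c("normal", "lognormal"))) {
    fail_field("family", "must be 'normal' or 'lognormal'")
  }
  family <- match.arg(family, c("normal", "lognormal"))
  d <- list(family = family, mean = mean, cv = cv)
  if (family == "normal") {
    d$sd <- cv * mean
  } else {
    d$sdlog <- sqrt(log(1 + cv^2))
    d$meanlog <- log(mean) - d$sdlog^2 / 2
  }
  structure(d, class = "intake_distribution")
}

#' Quantile of an intake distribution
#'
#' Normal-family quantiles are clamped at 0 (the negligible mass below zero at
#' CV 25% is re-assigned to an atom at 0, so clamped individuals are deficient
#' whenever the cut-point is positive).
#'
#' @param dist An [build_intake_distribution()] object.
#' @param u Probabilities in (0, 1); vectorized.
#' @return Intakes in mg/day.
#' @export
intake_quantile <- function(dist, u) {
  stopifnot(inherits(dist, "intake_distribution"))
  if (any(u <= 0 | u >= 1)) {
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (dist$family == "normal") {
    pmax(0, stats::qnorm(u, dist$mean, dist$sd))
  } else {
    stats::qlnorm(u, dist$meanlog, dist$sdlog)
  }
}

#' CDF of an intake distribution
#'
#' @param dist An [build_intake_distribution()] object.
#' @param x Intakes in mg/day; vectorized.
#' @return Probabilities.
#' @export
intake_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "intake_distribution"))
  if (dist$family == "normal") {
    stats::pnorm(x, dist$mean, dist$sd)
  } else {
    stats::plnorm(x, dist$meanlog, dist$sdlog)
  }
}

#' Population-weighted estimated average requirement
#'
#' The WtdEAR averages demographic-group estimated average requirements by the
#' population fraction in each group: `sum(requirements * weights)`.
#'
#' @param requirements Named numeric vector of per-group requirements, mg/day.
#' @param weights Named numeric vector of population fractions; names must
#'   match `requirements` and weights must sum to 1 (tolerance 1e-9).
#' @return WtdEAR in mg/day.
#' @examples
#' compute_wtdear(c(a = 10, b = 12), c(a = 0.6, b = 0.4))  # 10.8
#' @export
compute_wtdear <- function(requirements, weights) {
  if (is.null(names(requirements)) || is.null(names(weights)) ||
      !setequal(names(requirements), names(weights)) ||
      length(requirements) != length(weights)) {
    fail_field("group_requirements", "cells must match group_weights exactly")
  }
  weights <- weights[names(requirements)]
  if (abs(sum(weights) - 1) > 1e-9) {
    fail_field("group_weights", "must sum to 1 (tolerance 1e-9)")
  }
  if (any(requirements <= 0)) {
    fail_field("group_requirements", "must all be positive")
  }
  sum(requirements * weights)
}

#' Deficiency prevalence via the EAR cut-point method
#'
#' The EAR cut-point method classifies a person deficient when average intake
#' falls below the population-weighted estimated average requirement, so the
#' population prevalence is the intake CDF evaluated at the cut-point.
#'
#' @param dist An [build_intake_distribution()] object.
#' @param wtdear Cut-point in mg/day; must be positive.
#' @return Fraction of the population deficient, in \[0, 1\].
#' @export
deficiency_prevalence <- function(dist, wtdear) {
  check_number(wtdear, "wtdear", lower = 0, strict_lower = TRUE)
  intake_cdf(dist, wtdear)
}

#' Individual deficiency classification
#'
#' A simulated person carries a persistent intake quantile `u`; their intake in
#' a given year is the distribution quantile at `u`, and they are deficient iff
#' that intake is strictly below the cut-point (ties count as non-deficient).
#'
#' @param u Persistent intake quantiles in (0, 1); vectorized.
#' @param dist An [build_intake_distribution()] object.
#' @param wtdear Cut-point in mg/day.
#' @return Logical vector.
#' @export
is_deficient <- function(u, dist, wtdear) {
  intake_quantile(dist, u) < wtdear
}
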