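# Internal helpers: seed derivation, validation assertions, age-band lookup.

# Deterministic 32-bit-safe child seeds. Keeps every derived seed in
# [1, 2^31 - 2] so set.seed() never overflows.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  as.integer(((seed %% 1000003) * 10007 + (k %% 100003) * 97 + 1) %% 2147483646) + 1L
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    fail_field(field, "must be a single non-missing number")
  }
  if (x < lower || (strict_lower && x <= lower)) {
    fail_field(field, sprintf("must be %s %g", if (strict_lower) ">" else ">=", lower))
  }
  if (x > upper || (strict_upper && x >= upper)) {
    fail_field(field, sprintf("must be %s %g", if (strict_upper) "<" else "<=", upper))
  }
  invisible(x)
}

# Age bands used throughout: 0-4, 5-14, 15-49, 50+.
AGE_BANDS <- c("0-4", "5-14", "15-49", "50+")
AGE_BAND_BREAKS <- c(5, 15, 50)

age_band_index <- function(age) {
  findInterval(age, AGE_BAND_BREAKS) + 1L
}

age_band_label <- function(age) {
  AGE_BANDS[age_band_index(age)]
}

MODELED_DISEASES <- c("malaria", "pneumonia", "diarrhea", "ida")
WHO_REGIONS <- c("AFR", "AMR", "SEAR", "EUR", "EMR", "WPR")
SIM_YEARS <- 2015:2050
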