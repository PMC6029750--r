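# Numeric CDF oracle independent of pnorm(): adaptive quadrature of the
# normal density.
phi_oracle <- function(z) {
  stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), -Inf, z,
                   rel.tol = 1e-10)$value
}

test_that("build_intake_distribution matches its moment contracts", {
  d <- build_intake_distribution(10, 0.25, "normal")
  expect_equal(d$sd, 2.5)
  expect_equal(intake_quantile(d, 0.5), 10)

  # lognormal moment matching checked against a sampling oracle (1e6 draws)
  dl <- build_intake_distribution(10, 0.40, "lognormal")
  expect_equal(dl$sdlog^2, log(1 + 0.40^2), tolerance = 1e-12)
  expect_equal(dl$meanlog, log(10) - dl$sdlog^2 / 2, tolerance = 1e-12)
  draws <- withr::with_seed(1, rlnorm(1e6, dl$meanlog, dl$sdlog))
  expect_equal(mean(draws), 10, tolerance = 0.01)
  expect_equal(sd(draws) / mean(draws), 0.40, tolerance = 0.01)

  expect_error(build_intake_distribution(10, 0.25, "gamma"), "family")
  expect_error(build_intake_distribution(-1, 0.25), "mean")
  expect_error(build_intake_distribution(10, 1.2), "cv")
})

test_that("compute_wtdear is the weighted average of group requirements", {
  expect_equal(compute_wtdear(c(a = 8, b = 8, c = 8), c(a = 0.2, b = 0.3, c = 0.5)), 8)
  expect_equal(compute_wtdear(c(a = 10, b = 12), c(a = 0.6, b = 0.4)), 10.8)
  # groups calibrated to reproduce the Nigeria zinc cut-point of 10.33
  req <- c(u5 = 4.1, child = 8.0, adult_f = 9.0, adult_m = 14.0)
  w <- c(u5 = 0.16, child = 0.24, adult_f = 0.30, adult_m = 0.30)
  target <- 10.33
  req <- req * target / sum(req * w)
  expect_equal(compute_wtdear(req, w), 10.33, tolerance = 1e-12)

  expect_error(compute_wtdear(c(a = 10), c(b = 1)), "group_requirements")
  expect_error(compute_wtdear(c(a = 10, b = 2), c(a = 0.6, b = 0.5)), "group_weights")
})

test_that("deficiency_prevalence equals the intake CDF at the cut-point", {
  d <- build_intake_distribution(10, 0.25, "normal")
  expect_equal(deficiency_prevalence(d, 10), 0.5)
  # numeric quadrature oracle
  expect_equal(deficiency_prevalence(d, 10.33), phi_oracle(0.33 / 2.5),
               tolerance = 1e-8)
  # limit wtdear -> 0+: the clamped normal keeps an atom at 0 of mass
  # pnorm(-1/cv), so the prevalence floor is ~3.2e-5 at CV 25%; the
  # lognormal limit is exactly 0
  expect_lt(deficiency_prevalence(d, 1e-8), 1e-4)
  expect_lt(deficiency_prevalence(build_intake_distribution(10, 0.25, "lognormal"),
                                  1e-8), 1e-12)

  # closed-form agreement for both families at identical mean/CV
  dl <- build_intake_distribution(10, 0.25, "lognormal")
  expect_equal(deficiency_prevalence(dl, 8),
               plnorm(8, dl$meanlog, dl$sdlog), tolerance = 1e-9)
  expect_equal(deficiency_prevalence(d, 8), pnorm(8, 10, 2.5), tolerance = 1e-9)
})

test_that("deficiency_prevalence is monotone in mean and cut-point; declines raise it", {
  wtdear <- 10
  means <- seq(8, 14, by = 0.5)
  prev <- vapply(means, function(m) {
    deficiency_prevalence(build_intake_distribution(m, 0.25), wtdear)
  }, numeric(1))
  expect_true(all(diff(prev) < 0))

  cuts <- seq(6, 14, by = 0.5)
  prev2 <- vapply(cuts, function(w) {
    deficiency_prevalence(build_intake_distribution(10, 0.25), w)
  }, numeric(1))
  expect_true(all(diff(prev2) > 0))

  # multiplicative decline d > 0 on the mean strictly increases prevalence
  for (dcl in c(0.01, 0.05, 0.1)) {
    expect_gt(deficiency_prevalence(build_intake_distribution(10 * (1 - dcl), 0.25), 9),
              deficiency_prevalence(build_intake_distribution(10, 0.25), 9))
  }
})

test_that("is_deficient uses the persistent quantile with a strict-< tie rule", {
  d <- build_intake_distribution(10, 0.25, "normal")
  expect_false(is_deficient(0.5, d, 10))  # tie resolves non-deficient
  expect_true(is_deficient(0.01, d, 10))
  expect_false(is_deficient(0.99, d, 10))
  expect_error(is_deficient(0, d, 10), "u must lie")
  expect_error(is_deficient(1, d, 10), "u must lie")

  # monotone in u: deficient exactly below the CDF at the cut-point
  u <- seq(0.001, 0.999, by = 0.001)
  def <- is_deficient(u, d, 10.33)
  expect_true(all(def == (u < deficiency_prevalence(d, 10.33))))
})

test_that("Monte Carlo deficient fraction matches the analytic CDF", {
  n <- 1e5
  for (fam in c("normal", "lognormal")) {
    cv <- if (fam == "normal") 0.25 else 0.40
    d <- build_intake_distribution(12, cv, fam)
    u <- withr::with_seed(11, runif(n))
    frac <- mean(is_deficient(u, d, 10.5))
    p <- deficiency_prevalence(d, 10.5)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(frac - p), 3 * se)
  }
})
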