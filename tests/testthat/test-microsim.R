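test_that("project_rate continues the annual percent change exponentially", {
  expect_equal(project_rate(0.05, 0, 2040), 0.05)
  expect_equal(project_rate(0.05, -0.02, 2016), 0.049)
  expect_equal(project_rate(0.038, -0.02, 2050), 0.038 * 0.98^35, tolerance = 1e-12)
  expect_equal(project_rate(0.038, -0.02, 2050), 0.01873, tolerance = 1e-3)
  # vectorized over years, closed form to 1e-12
  yrs <- 2015:2050
  expect_equal(project_rate(0.2, 0.013, yrs), 0.2 * 1.013^(yrs - 2015),
               tolerance = 1e-12)
  expect_error(project_rate(0.05, -1, 2020), "apc")
  expect_error(project_rate(-0.1, 0, 2020), "rate_2015")
})

test_that("partition_rate_by_deficiency preserves the population average exactly", {
  expect_equal(partition_rate_by_deficiency(0.1, 0.5, 1),
               c(nondeficient = 0.1, deficient = 0.1))
  p <- partition_rate_by_deficiency(0.10, 0.5, 1.5)
  expect_equal(unname(p), c(0.08, 0.12))
  expect_equal(0.5 * p[["nondeficient"]] + 0.5 * p[["deficient"]], 0.10)
  expect_equal(partition_rate_by_deficiency(0.07, 0, 2)[["nondeficient"]], 0.07)

  # property: the weighted mean recovers the average for random (avg, f, rr)
  set.seed(5)
  for (i in 1:50) {
    avg <- runif(1, 0, 0.5); f <- runif(1); rr <- 1 + runif(1, 0, 3)
    pr <- partition_rate_by_deficiency(avg, f, rr)
    expect_equal((1 - f) * pr[["nondeficient"]] + f * pr[["deficient"]], avg,
                 tolerance = 1e-12)
    expect_equal(pr[["deficient"]], rr * pr[["nondeficient"]], tolerance = 1e-12)
  }

  # infinite RR assigns everything to the deficient stratum
  pi <- partition_rate_by_deficiency(0.02, 0.25, Inf)
  expect_equal(unname(pi), c(0, 0.08))
  expect_error(partition_rate_by_deficiency(0.1, 0.5, 0.8), "rr")
})

test_that("init_population is deterministic and matches the demographic weights", {
  p <- tiny_profile()
  expect_identical(init_population(p, 1000, seed = 5),
                   init_population(p, 1000, seed = 5))
  pop1 <- init_population(p, 1, seed = 3)
  expect_length(pop1$age, 1)
  expect_true(pop1$alive)

  pop <- init_population(p, 1e5, seed = 9)
  w_u5 <- sum(p$demography$weight[p$demography$age_band == "0-4"])
  frac <- mean(pop$age < 5)
  se <- sqrt(w_u5 * (1 - w_u5) / 1e5)
  expect_lt(abs(frac - w_u5), 3 * se)
  w_f <- sum(p$demography$weight[p$demography$sex == "female"])
  expect_lt(abs(mean(pop$sex == "female") - w_f), 3 * sqrt(w_f * (1 - w_f) / 1e5))
  expect_error(init_population(p, 0, seed = 1), "n")
})

test_that("a zero-disease profile yields a zero burden slice", {
  p <- zero_disease_profile()
  pop <- init_population(p, 500, seed = 1)
  step <- simulate_year(pop, p, 2015, co2_scenario())
  expect_equal(unname(step$slice$yll), rep(0, 4))
  expect_equal(unname(step$slice$yld), rep(0, 4))
  expect_equal(unname(step$slice$deaths), rep(0, 4))
})

test_that("null models give exactly zero attributable burden (common random numbers)", {
  p <- no_decline_profile()
  for (s in c(1, 7, 23)) {
    r <- run_paired(p, n = 500, seed = s)
    expect_identical(r$attributable_dalys, 0)
    expect_equal(max(abs(r$attributable$yll)), 0)
    expect_equal(max(abs(r$attributable$deaths)), 0)
  }
  # full climate mitigation is the same null
  p2 <- tiny_profile()
  r2 <- run_paired(p2, strategy = mitigation_strategy("paris", fraction_rise_prevented = 1),
                   n = 500, seed = 4)
  expect_identical(r2$attributable_dalys, 0)
})

test_that("rr = 1 everywhere plus zero declines keeps arms identical", {
  p <- no_decline_profile()
  for (d in c("malaria", "pneumonia", "diarrhea")) {
    p$disease_epi[[d]]$rr_given_zinc_deficient <- 1
  }
  r <- run_paired(p, n = 400, seed = 11, options = microsim_options(rr_ida = 1))
  expect_identical(r$exposed, r$counterfactual)
})

test_that("baseline-arm disease rates reproduce the projected inputs (partition identity)", {
  p <- tiny_profile()
  n <- 1e5
  pop <- init_population(p, n, seed = 21)
  # expected malaria person-time in the 2015 baseline year vs the input
  step <- simulate_year(pop, p, 2015, co2_scenario(fraction_rise_prevented = 1))
  implied_prev <- step$slice$yld[["malaria"]] /
    p$disease_epi$malaria$disability_weight / step$slice$person_years
  expected <- p$disease_epi$malaria$prevalence_2015
  # YLD accrual is deterministic given deficiency status, so the only noise is
  # the under-5-and-zinc-deficient head count: implied - expected =
  # rate_nd * (rr - 1) * (f_hat - f), giving the 3-SE band below
  rr <- p$disease_epi$malaria$rr_given_zinc_deficient
  f <- sum(p$demography$weight[p$demography$age_band == "0-4"]) *
    deficiency_prevalence(
      build_intake_distribution(per_capita_supply(p, "zinc", 2015),
                                p$intake_cv_zinc),
      p$wtdear_zinc)
  se_f <- sqrt(f * (1 - f) / n)
  band <- 3 * (rr - 1) * se_f / (1 + (rr - 1) * f)
  expect_lt(abs(implied_prev - expected) / expected, band)
})

test_that("run_paired is fully reproducible and accounts DALYs consistently", {
  p <- tiny_profile()
  r1 <- run_paired(p, n = 800, seed = 13)
  r2 <- run_paired(p, n = 800, seed = 13)
  expect_identical(r1, r2)

  # DALY = YLL + YLD per cause-year, exactly
  expect_identical(dalys(r1$exposed), r1$exposed$yll + r1$exposed$yld)
  # person-years bookkeeping: deaths never exceed the living
  expect_true(all(rowSums(r1$exposed$deaths) <= r1$exposed$person_years))
  # attributable burden is non-negative in expectation; a single run at this
  # size is already reliably positive for a high-burden profile
  expect_gt(r1$attributable_dalys, 0)
  # per-1,000 normalization recovers the raw attributable burden
  expect_equal(r1$dalys_per_1000 * r1$n_initial / 1000, r1$attributable_dalys,
               tolerance = 1e-9)
})

test_that("attributable burden responds to the decline magnitude (small-scale check)", {
  base <- tiny_profile()
  out <- vapply(c(0, 0.10), function(dcl) {
    p <- base
    p$foods$zinc_decline_2050 <- dcl
    p$foods$iron_decline_2050 <- dcl
    mean(vapply(1:5, function(s) {
      run_paired(p, n = 2000, seed = s)$attributable_dalys
    }, numeric(1)))
  }, numeric(1))
  expect_identical(out[1], 0)
  expect_gt(out[2], 0)
})
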