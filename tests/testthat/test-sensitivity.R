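# Linear-interpolation percentile oracle, independent of stats::quantile().
percentile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

test_that("credible_interval matches the linear-interpolation percentile oracle", {
  expect_equal(credible_interval(1:100, 0.95), c(3.475, 97.525))
  set.seed(2)
  for (i in 1:10) {
    draws <- rnorm(50 + i)
    lvl <- runif(1, 0.5, 0.99)
    expect_equal(credible_interval(draws, lvl),
                 c(percentile_oracle(draws, (1 - lvl) / 2),
                   percentile_oracle(draws, 1 - (1 - lvl) / 2)),
                 tolerance = 1e-12)
  }
  expect_equal(credible_interval(rep(4.2, 10)), c(4.2, 4.2))
  # shrinking level collapses toward the median
  d <- rnorm(101)
  tiny <- credible_interval(d, 1e-6)
  expect_equal(tiny[1], median(d), tolerance = 1e-3)
  expect_equal(tiny[2], median(d), tolerance = 1e-3)
  expect_error(credible_interval(1), "draws")
  expect_error(credible_interval(1:10, 1), "level")
})

test_that("parameter paths resolve, perturb, and clamp to natural bounds", {
  p <- tiny_profile()
  expect_equal(get_param(p, "wtdear_iron"), p$wtdear_iron)
  expect_equal(get_param(p, "disease_epi.malaria.prevalence_2015"),
               p$disease_epi$malaria$prevalence_2015)
  expect_equal(get_param(p, "foods.c3_grain.supply_kcal"),
               p$foods$supply_kcal[p$foods$category == "c3_grain"])
  expect_error(get_param(p, "no.such.path"), "parameter_path")

  p2 <- perturb_profile(p, "wtdear_zinc", 1.1)
  expect_equal(p2$wtdear_zinc, p$wtdear_zinc * 1.1)
  # clamping: a disability weight near 1 cannot exceed 1
  p3 <- tiny_profile()
  p3$disease_epi$malaria$disability_weight <- 0.95
  p4 <- perturb_profile(p3, "disease_epi.malaria.disability_weight", 1.1)
  expect_equal(p4$disease_epi$malaria$disability_weight, 1)
  # demography weights renormalize
  p5 <- perturb_profile(p, "demography.0-4.female.weight", 1.1)
  expect_equal(sum(p5$demography$weight), 1, tolerance = 1e-12)
})

test_that("one-way spreads: null parameters give zero, iron inputs rank high", {
  p <- tiny_profile()
  # iron-marginal profile: mean iron intake close to the cut-point
  params <- c("wtdear_iron", "wtdear_zinc",
              "disease_epi.pneumonia.disability_weight",
              "disease_epi.malaria.prevalence_2015")
  # pneumonia with zero prevalence AND zero mortality has no causal path
  p$disease_epi$pneumonia$prevalence_2015 <- 0
  p$disease_epi$pneumonia$mortality_2015 <- 0
  tor <- one_way(p, parameters = params, n = 1500, reps = 2, seed = 2)
  expect_equal(tor$spread[tor$parameter == "disease_epi.pneumonia.disability_weight"], 0)
  # WtdEARs shift the whole deficiency pathway and dominate a prevalence tweak
  expect_true("wtdear_iron" %in% tor$parameter[1:2])
  # order invariance: same spreads regardless of parameter listing order
  tor_rev <- one_way(p, parameters = rev(params), n = 1500, reps = 2, seed = 2)
  expect_equal(tor[order(tor$parameter), c("parameter", "low", "high")],
               tor_rev[order(tor_rev$parameter), c("parameter", "low", "high")],
               ignore_attr = TRUE)
})

test_that("one-way with unit multipliers reproduces the unperturbed outcome", {
  p <- tiny_profile()
  base <- mean(vapply(1:2, function(r) {
    run_paired(p, n = 1000, seed = nutrisim:::derive_seed(4, 300 + r))$dalys_per_1000
  }, numeric(1)))
  # perturbing by exactly 1.0 is the unperturbed model under the same seeds
  p_same <- perturb_profile(p, "wtdear_zinc", 1)
  same <- mean(vapply(1:2, function(r) {
    run_paired(p_same, n = 1000, seed = nutrisim:::derive_seed(4, 300 + r))$dalys_per_1000
  }, numeric(1)))
  expect_identical(base, same)
})

test_that("probabilistic summaries are deterministic and degenerate at zero input SD", {
  p <- tiny_profile()
  params <- c("wtdear_zinc", "wtdear_iron")
  s0 <- probabilistic(p, parameters = params, rel_sd = 0, n_draws = 4,
                      n = 500, seed = 6)
  expect_equal(s0$ci_low, s0$mean)
  expect_equal(s0$ci_high, s0$mean)
  expect_equal(s0$sd, 0)

  s1 <- probabilistic(p, parameters = params, rel_sd = 0.1, n_draws = 6,
                      n = 500, seed = 6)
  s2 <- probabilistic(p, parameters = params, rel_sd = 0.1, n_draws = 6,
                      n = 500, seed = 6)
  expect_identical(s1$draws, s2$draws)
  expect_true(s1$ci_low <= s1$mean && s1$mean <= s1$ci_high)
  expect_error(probabilistic(p, n_draws = 1), "n_draws")
})

test_that("CrI coverage on a linear toy outcome matches the closed form", {
  # a linear outcome of a Normal(mu, sd) input has the closed-form 95%
  # interval mu +/- 1.96 sd; the empirical percentile interval must agree
  # within Monte Carlo error
  mu <- 10; sd_in <- 1
  draws <- withr::with_seed(8, 3 + 2 * rnorm(4000, mu, sd_in))  # outcome = 3 + 2x
  lo_hi <- credible_interval(draws, 0.95)
  expect_equal(lo_hi[1], 3 + 2 * (mu - 1.96 * sd_in), tolerance = 0.01)
  expect_equal(lo_hi[2], 3 + 2 * (mu + 1.96 * sd_in), tolerance = 0.01)
})
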