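test_that("conditional middle mean shifts linearly in the covariate", {
  sc <- scenario_80_15_5()
  expect_equal(conditional_middle_mean(sc, 1, 14), 15 + 0.15 * 14)  # 17.1
  expect_equal(conditional_middle_mean(sc, 0, 30), 20 + 0.15 * 30)  # 24.5
  expect_equal(conditional_middle_mean(sc, 1, 0), 15)
  expect_equal(conditional_middle_mean(sc, 0, 0), 20)
  expect_error(conditional_middle_mean(sc, 0, 400), "outside")
})

test_that("scenario validation rejects means that leave the outcome range", {
  expect_error(scenario_config(
    n_obs = 100, probs0 = c(0.6, 0.3, 0.1), probs1 = c(0.8, 0.15, 0.05),
    mid_mean0 = 55, mid_mean1 = 15, mid_sd0 = 14, mid_sd1 = 13,
    slope_a = 0.15), "leaves")
})

test_that("scenarios round-trip through YAML", {
  sc <- scenario_80_15_5(n_obs = 150)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$n_obs, 150L)
  expect_equal(sc2$probs1, sc$probs1)
  expect_equal(sc2$mid_sd0, sc$mid_sd0)
  expect_equal(sc2$covariate$p_zero, 0.30)
  expect_equal(sc2$label, sc$label)
})

test_that("covariate draws have the specified mixture structure", {
  cov <- covariate_params(p_zero = 0.3, mu_x = 20, sd_x = 16, max = 60)
  set.seed(7)
  x <- sample_covariates(cov, 1e6)
  expect_true(all(x >= 0 & x <= 59))
  expect_true(all(x == round(x)))
  # zero fraction ~ 0.30 within 4 binomial MC SEs
  se0 <- sqrt(0.3 * 0.7 / 1e6)
  expect_lt(abs(mean(x == 0) - 0.3), 4 * se0)
  # overall mean ~ (1 - 0.3) * 20 = 14 within 4 MC SEs
  expect_lt(abs(mean(x) - 14), 4 * sd(x) / 1000)
  # degenerate zero-inflation
  expect_true(all(sample_covariates(covariate_params(p_zero = 1 - 1e-12),
                                    100) == 0))
})

test_that("simulated trials are bit-reproducible and respect the support", {
  sc <- scenario_80_15_5()
  d1 <- simulate_trial(sc, seed = 123)
  d2 <- simulate_trial(sc, seed = 123)
  expect_identical(d1, d2)
  expect_equal(sum(d1$arm == 0), 100)
  expect_equal(sum(d1$arm == 1), 100)
  expect_true(all(d1$y %in% 0:60))
  expect_true(all(d1$x %in% 0:59))
  d3 <- simulate_trial(sc, seed = 124)
  expect_false(identical(d1, d3))
})

test_that("compiling a scenario up front does not change the draws", {
  sc <- scenario_80_15_5()
  expect_identical(simulate_trial(sc, seed = 5),
                   simulate_trial(compile_scenario(sc), seed = 5))
})

test_that("a scenario with (almost) all mass on zero loss yields all-zero outcomes", {
  eps <- 1e-9
  sc <- scenario_config(
    n_obs = 500,
    probs0 = c(1 - 2 * eps, eps, eps), probs1 = c(1 - 2 * eps, eps, eps),
    mid_sd0 = 14.63, mid_sd1 = 13.34)
  d <- simulate_trial(sc, seed = 9)
  expect_true(all(d$y == 0))
})

test_that("category frequencies and middle-part moments match the generating law", {
  sc <- scenario_80_15_5(n_obs = 1e5)
  d <- simulate_trial(sc, seed = 31)
  at0 <- d[d$x == 0, ]
  for (arm in 0:1) {
    sub <- at0[at0$arm == arm, ]
    n <- nrow(sub)
    triple <- if (arm == 1) sc$probs1 else sc$probs0
    freqs <- c(mean(sub$y == 0), mean(sub$y > 0 & sub$y < 60),
               mean(sub$y == 60))
    for (j in 1:3) {
      se <- sqrt(triple[j] * (1 - triple[j]) / n)
      expect_lt(abs(freqs[j] - triple[j]), 4 * se)
    }
  }
  # middle-part conditional mean at x = 0, arm 1 is 15
  mid1 <- at0$y[at0$arm == 1 & at0$y > 0 & at0$y < 60]
  expect_lt(abs(mean(mid1) - 15), 4 * sd(mid1) / sqrt(length(mid1)))
  # and its SD is 13.34 (equal-scale arm 1)
  expect_lt(abs(sd(mid1) - 13.34), 4 * sd(mid1) / sqrt(2 * length(mid1)))
})

test_that("trial datasets round-trip through CSV", {
  d <- fixture_trial(n_obs = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  d2 <- read_trial_csv(path)
  expect_equal(d2$y, d$y)
  expect_equal(d2$x, d$x)
  expect_s3_class(d2, "trial_data")
})
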