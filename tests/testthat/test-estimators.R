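# Cross-checks of the internal ML engines against reference fitters on
# well-behaved data, plus the plug-in effect compositions.

test_that("OLS reproduces lm, with the arm coefficient as the effect", {
  d <- fixture_trial()
  f <- fit_ols(d)
  ref <- stats::lm(y ~ arm + x, data = d)
  expect_equal(unname(f$parts$mean$coef), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(f$parts$mean$se[2]),
               unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-10)
  # effect is the arm coefficient, identical at every x
  eff <- effect_at(f, c(0, 14, 30))
  expect_equal(eff, rep(unname(coef(ref)[2]), 3))
})

test_that("a saturated zero/max contrast gives effect 60 even with constant x", {
  d <- data.frame(arm = rep(0:1, each = 20), x = 0,
                  y = rep(c(0, 60), each = 20))
  f <- fit_ols(d)
  expect_true(f$converged)
  expect_equal(unname(effect_at(f, c(0, 14, 30))), rep(60, 3))
})

test_that("logistic and Gamma engines match stats::glm", {
  d <- fixture_trial()
  X <- cbind(1, d$arm, d$x)
  lf <- plossim:::logit_fit(X, as.numeric(d$y == 0))
  ref <- stats::glm(I(y == 0) ~ arm + x, data = d, family = binomial())
  expect_equal(unname(lf$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_false(lf$separated)
  pos <- d$y > 0
  gf <- plossim:::gamma_fit(X[pos, ], d$y[pos])
  refg <- stats::glm(y ~ arm + x, data = d[pos, ],
                     family = Gamma(link = "log"))
  expect_equal(unname(gf$coef), unname(coef(refg)), tolerance = 1e-5)
})

test_that("the NB engine matches MASS::glm.nb where the latter converges", {
  skip_if_not_installed("MASS")
  set.seed(11)
  n <- 4000
  arm <- rep(0:1, each = n / 2)
  x <- rpois(n, 10)
  y <- stats::rnbinom(n, size = 1.5, mu = exp(1 + 0.5 * arm + 0.03 * x))
  f <- plossim:::nb_ml(cbind(1, arm, x), y)
  ref <- MASS::glm.nb(y ~ arm + x)
  expect_equal(unname(f$coef), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(f$size), unname(ref$theta), tolerance = 1e-3)
})

test_that("the multinomial engine matches nnet::multinom", {
  skip_if_not_installed("nnet")
  d <- fixture_trial()
  K <- 1L + (d$y > 0) + (d$y >= 60)
  f <- plossim:::mlogit_ml(cbind(1, d$arm, d$x), K)
  ref <- nnet::multinom(factor(K, levels = c(3, 1, 2)) ~ arm + x,
                        data = d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(c(f$coef1, f$coef2)),
               unname(as.vector(t(coef(ref)))), tolerance = 1e-4)
  expect_true(f$converged)
  expect_false(f$separated)
})

test_that("the zero-truncated NB engine recovers known parameters", {
  # oracle: rejection sampling from an untruncated NB, dropping zeros
  set.seed(21)
  n <- 6000
  arm <- rep(0:1, each = n / 2)
  x <- rpois(n, 8)
  mu <- exp(2 + 0.4 * arm + 0.02 * x)
  y <- stats::rnbinom(n, size = 2, mu = mu)
  keep <- y > 0
  f <- plossim:::ztnb_ml(cbind(1, arm, x)[keep, ], y[keep])
  expect_true(f$converged)
  expect_lt(max(abs(f$coef - c(2, 0.4, 0.02))), 0.12)
  expect_lt(abs(f$size - 2), 0.4)
  # implied conditional mean E(Y | Y > 0) vs the empirical truncated mean
  mu_hat <- exp(sum(f$coef * c(1, 0, 8)))
  expect_lt(abs(plossim:::ztnb_cond_mean(mu_hat, f$size) -
                  mean(y[keep & arm == 0 & x == 8])), 1)
})

test_that("the Beta engine recovers known regression parameters", {
  set.seed(31)
  n <- 6000
  arm <- rep(0:1, each = n / 2)
  x <- runif(n, 0, 30)
  mu <- stats::plogis(-0.5 + 0.3 * arm + 0.01 * x)
  phi <- 5
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  f <- plossim:::beta_ml(cbind(1, arm, x), y)
  expect_true(f$converged)
  expect_lt(max(abs(f$coef - c(-0.5, 0.3, 0.01))), 0.1)
  expect_lt(abs(f$phi - 5), 0.5)
})

test_that("hurdle variants share the zero part and compose the plug-in effect", {
  d <- fixture_trial()
  f1 <- fit_two_part(d, "zero_truncated_nb")
  f2 <- fit_two_part(d, "gamma")
  expect_identical(f1$parts$zero$coef, f2$parts$zero$coef)
  expect_equal(f1$kind, "ztnb")
  expect_equal(f2$kind, "zg")
  # effect composition: (1 - p0) * positive-part mean, per arm, by hand
  for (f in list(f1, f2)) {
    zc <- f$parts$zero$coef; pc <- f$parts$positive$coef
    x <- 14
    m <- function(arm) {
      mu <- exp(pc[1] + pc[2] * arm + pc[3] * x)
      if (f$kind == "ztnb")
        mu <- plossim:::ztnb_cond_mean(mu, f$parts$positive$size)
      (1 - stats::plogis(zc[1] + zc[2] * arm + zc[3] * x)) * mu
    }
    expect_equal(unname(effect_at(f, 14)), unname(m(1) - m(0)),
                 tolerance = 1e-10)
  }
})

test_that("all-equal positive outcomes give zero estimated effect", {
  d <- data.frame(arm = rep(0:1, each = 30), x = rep(0:29, 2), y = 5)
  f <- fit_nb(d)
  expect_lt(abs(effect_at(f, 14)), 1e-4)
})

test_that("effect estimates are invariant to record order", {
  d <- fixture_trial()
  set.seed(3)
  d2 <- d[sample.int(nrow(d)), ]
  for (k in c("ols", "nb", "ztnb", "zg", "three_part")) {
    e1 <- effect_at(fit_model(d, k), c(0, 14, 30))
    e2 <- effect_at(fit_model(d2, k), c(0, 14, 30))
    expect_equal(e1, e2, tolerance = 1e-6)
  }
})

test_that("three-part fitting requires every category in both arms", {
  d <- fixture_trial()
  d_nomax <- d[!(d$arm == 1 & d$y == 60), ]
  expect_error(fit_three_part(d_nomax), "three outcome categories")
})

test_that("zero arm contrasts give zero three-part effect", {
  # symmetric arms: fit on data where arm labels are randomised
  d <- fixture_trial(n_obs = 400)
  set.seed(17)
  d$arm <- sample(d$arm)
  f <- fit_three_part(d)
  # arm coefficients are noise around 0, so the effect is near 0
  expect_lt(abs(effect_at(f, 14)), 2.5)
})

test_that("textbook complete separation is flagged, well-mixed data are not", {
  x <- c(1:20, 31:50)
  d <- data.frame(arm = rep(0:1, 20), x = x, y = ifelse(x > 25, 0, x))
  f <- fit_two_part(d, "gamma")
  expect_true(detect_separation(d, f))
  d2 <- fixture_trial()
  expect_false(detect_separation(d2, fit_two_part(d2, "gamma")))
  expect_false(detect_separation(d2, fit_three_part(d2)))
})

test_that("large-sample effect estimates are consistent for the truth", {
  sc <- scenario_50_40_10(n_obs = 1e5)
  sc <- compile_scenario(sc)
  d <- simulate_trial(sc, seed = 77)
  th14 <- true_effect(sc, 14)
  # OLS: model-based SE available
  f <- fit_ols(d)
  expect_lt(abs(effect_at(f, 14) - th14), 4 * f$parts$mean$se[2])
  # remaining models: compare against the n = 100 empirical SE scaled to
  # this sample size (about 3 / sqrt(1000) ~ 0.1 days)
  for (k in c("ztnb", "zg", "three_part")) {
    eff <- effect_at(fit_model(d, k), 14)
    expect_lt(abs(eff - th14), 0.5)
  }
})

test_that("inference composes estimates, intervals and tests coherently", {
  d <- fixture_trial()
  res <- effect_with_inference(d, "ols", x_points = c(0, 14, 30))
  f <- fit_ols(d)
  se <- f$parts$mean$se[2]
  expect_equal(res$ci_low, res$theta_hat - 1.96 * se, ignore_attr = TRUE)
  expect_equal(res$ci_high, res$theta_hat + 1.96 * se, ignore_attr = TRUE)
  expect_equal(res$se_method, rep("model", 3))
  expect_true(all(res$ci_low <= res$theta_hat & res$theta_hat <= res$ci_high))
  # bootstrap route returns finite SEs and counts failures
  res2 <- effect_with_inference(d, "zg", x_points = 14, B = 50, seed = 5)
  expect_true(is.finite(res2$se))
  expect_equal(res2$se_method, "bootstrap")
  expect_gte(res2$boot_failed, 0)
})
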