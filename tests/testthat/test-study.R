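test_that("the default grid spans 3 probability configs x 2 scales x 3 arm sizes", {
  plan <- build_default_grid()
  expect_length(plan$scenarios, 18)
  expect_equal(plan$n_sim, 5000L)
  expect_equal(plan$B, 1000L)
  expect_equal(plan$x_points, c(0, 14, 30))
  labels <- vapply(plan$scenarios, function(s) s$label, "")
  expect_equal(sum(grepl("80:15:5", labels)), 6)
  expect_equal(sum(grepl("unequal", labels)), 9)
  # equal-scale arm-1 SD is 13.34; unequal 12.00
  eq <- plan$scenarios[[which(grepl("80:15:5.*equal scale, n=100", labels) &
                                !grepl("unequal", labels))[1]]]
  expect_equal(eq$mid_sd1, 13.34)
  expect_equal(eq$mid_sd0, 14.63)
  uneq <- plan$scenarios[[which(grepl("80:15:5.*unequal", labels))[1]]]
  expect_equal(uneq$mid_sd1, 12)
  expect_equal(uneq$mid_sd0, 16)
  # shared parameters
  expect_equal(eq$gamma1, -0.02)
  expect_equal(eq$gamma2, -0.01)
  expect_equal(eq$slope_a, 0.15)
  expect_equal(eq$covariate$p_zero, 0.30)
})

test_that("small-arm applicability rules exclude fragile models", {
  # 50 per arm with 80% zero loss: no model comparison at all
  expect_length(applicable_models(scenario_80_15_5(n_obs = 50)), 0)
  # 50 per arm with 5% max loss: three-part excluded
  sc <- scenario_config(n_obs = 50, probs0 = c(0.40, 0.50, 0.10),
                        probs1 = c(0.60, 0.35, 0.05),
                        mid_sd0 = 14.63, mid_sd1 = 13.34)
  expect_setequal(applicable_models(sc),
                  c("ols", "nb", "ztnb", "zg"))
  # 100 per arm: all five
  expect_setequal(applicable_models(scenario_80_15_5(n_obs = 100)),
                  c("ols", "nb", "ztnb", "zg", "three_part"))
  expect_setequal(applicable_models(scenario_50_40_10(n_obs = 50)),
                  c("ols", "nb", "ztnb", "zg", "three_part"))
})

test_that("replicate seeds stay below 2^31 and differ across replicates", {
  seeds <- vapply(1:2000, function(r) plossim:::replicate_seed(42, 3, r),
                  integer(1))
  expect_true(all(seeds > 0))
  expect_true(all(seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
  expect_false(plossim:::replicate_seed(42, 1, 1) ==
                 plossim:::replicate_seed(43, 1, 1))
})

test_that("scenario runs are deterministic given the master seed", {
  sc <- scenario_50_40_10(n_obs = 60)
  r1 <- run_scenario(sc, n_sim = 3, B = 30, master_seed = 7)
  r2 <- run_scenario(sc, n_sim = 3, B = 30, master_seed = 7)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$ledger, r2$ledger)
  r3 <- run_scenario(sc, n_sim = 3, B = 30, master_seed = 8)
  expect_false(identical(r1$estimates, r3$estimates))
})

test_that("the convergence ledger accounts for every replicate", {
  sc <- scenario_50_40_10(n_obs = 60)
  res <- run_scenario(sc, n_sim = 4, B = 25, master_seed = 1)
  led <- res$ledger
  hist_cols <- c("0", "1-10", "11-100", "101-400", "401-700", "701-950",
                 ">950")
  expect_true(all(hist_cols %in% names(led)))
  # bootstrap histogram rows count the replicates that reached the
  # bootstrap stage for each non-OLS model
  for (m in setdiff(led$model, "ols")) {
    row <- led[led$model == m, ]
    attempted <- row$n_sim - row$n_nonconverged - row$n_separated
    expect_equal(sum(unlist(row[hist_cols])), attempted)
  }
})

test_that("runs without bootstrap keep OLS model SEs and skip the rest", {
  sc <- scenario_50_40_10(n_obs = 60)
  res <- run_scenario(sc, n_sim = 3, bootstrap = FALSE, master_seed = 2)
  est <- res$estimates
  expect_true(all(is.finite(est$se[est$model == "ols"])))
  expect_true(all(is.na(est$se[est$model != "ols"])))
  expect_true(all(est$se_method[est$model == "ols"] == "model"))
})

test_that("checkpointed estimates can be re-summarised without re-simulation", {
  sc <- scenario_50_40_10(n_obs = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  res <- run_scenario(sc, n_sim = 3, bootstrap = FALSE, master_seed = 2,
                      checkpoint = path, checkpoint_every = 2)
  expect_true(file.exists(path))
  est <- read.csv(path)
  expect_equal(nrow(est), nrow(res$estimates))
  perf_file <- performance_table(est, true_effect_curve(sc))
  perf_mem <- performance_table(res$estimates, true_effect_curve(sc))
  expect_equal(perf_file$bias, perf_mem$bias, tolerance = 1e-12)
})

test_that("run_study stitches scenarios, truth and performance together", {
  plan <- build_default_grid(n_obs = 60, n_sim = 2, B = 10, seed = 5)
  plan$scenarios <- plan$scenarios[1:2]
  res <- run_study(plan, bootstrap = FALSE)
  expect_true(all(c("estimates", "ledger", "truth", "performance")
                  %in% names(res)))
  expect_equal(sort(unique(res$estimates$scenario)),
               sort(vapply(plan$scenarios, function(s) s$label, "")))
  expect_s3_class(res$performance, "performance_table")
})
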