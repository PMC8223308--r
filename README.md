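# plossim

Simulation framework for **zero- and max-inflated productivity loss
outcomes** in two-arm randomised controlled trials.

## The problem

Work time lost to health problems over a fixed follow-up window (say 60
working days in 12 weeks) is a bounded outcome with probability mass piled
up at both ends: a large share of participants lose *no* time, and a
non-trivial share stop working and lose *all* of it. Trial analysts
routinely model such outcomes with ordinary least squares or a count GLM,
or with models built for the inflation — hurdle (two-part) models and a
three-part model. This package provides the machinery to decide, by
simulation, which strategy to trust when the quantity of interest is the
conditional treatment effect

> θ(x) = E{Y(1, x)} − E{Y(0, x)}

at chosen values x of a single baseline covariate (baseline productivity
loss).

It implements, as first-class tested code:

* **The data-generating mechanism** — multinomial-logit category
  membership (zero / some / max loss) in arm and covariate; a
  doubly-truncated negative binomial middle part parameterised by its
  truncated mean and SD (moment-matching solver included), with the
  conditional mean shifting linearly in the covariate; a zero-inflated
  truncated-NB baseline covariate.
* **The analytic truth** — θ(x) by the plug-in formula
  P₂·(mid mean + a·x) + P₃·Max per arm.
* **Five estimators** — OLS, negative binomial GLM, hurdle models with
  zero-truncated-NB or Gamma positive parts, and a multinomial-logit +
  Beta-regression three-part model, each composed into a plug-in estimate
  of θ(x), with stratified-bootstrap or model-based standard errors and
  quasi-complete-separation diagnostics.
* **Monte Carlo performance measures** — bias, coverage, power, empirical
  and model SE, MSE, each with its Monte Carlo standard error, plus the
  scenario grid, seeded replication loop and convergence bookkeeping.

## Worked example

```r
library(plossim)

sc <- scenario_config(
  n_obs = 100,
  probs0 = c(0.60, 0.30, 0.10),   # arm 0: P(zero), P(some), P(max) at x = 0
  probs1 = c(0.80, 0.15, 0.05),   # arm 1
  mid_sd0 = 14.63, mid_sd1 = 13.34,
  label = "80:15:5/60:30:10, equal scale")

true_effect(sc, c(0, 14, 30))
#> [1] -6.750000 -7.784932 -8.957279
```

The treatment reduces expected loss by 6.75 days for a participant with no
baseline loss, and by 8.96 days at 30 days of baseline loss (the effect
grows with x because the category probabilities and the middle-part mean
both depend on it). One simulated trial, analysed with the three-part
model and 1000 stratified bootstrap resamples:

```r
d <- simulate_trial(sc, seed = 1)
effect_with_inference(d, "three_part", x_points = c(0, 14, 30),
                      B = 1000, seed = 2)
#>        model  x theta_hat    se  ci_low ci_high reject_null se_method boot_failed
#> 1 three_part  0    -2.611 2.314  -7.147   1.924       FALSE bootstrap           0
#> 2 three_part 14    -3.221 2.614  -8.345   1.902       FALSE bootstrap           0
#> 3 three_part 30    -3.999 3.190 -10.252   2.254       FALSE bootstrap           0
```

This particular draw underestimates the effect and none of the intervals
exclude zero — at 100 per arm the estimator SD is close to 3 days. The
Monte Carlo loop quantifies exactly that:

```r
res <- run_scenario(sc, n_sim = 200, bootstrap = FALSE, master_seed = 1)
perf <- performance_table(res$estimates, true_effect_curve(sc))
perf[perf$model %in% c("ols", "three_part"),
     c("model", "x", "bias", "empirical_se", "mse", "coverage")]
#>         model  x    bias empirical_se  mse coverage
#> 1         ols  0 -0.8589         2.58 7.35    0.955
#> 2         ols 14  0.1760         2.58 6.64    0.950
#> 3         ols 30  1.3484         2.58 8.43    0.940
#> 13 three_part  0  0.0538         2.37 5.57      NaN
#> 14 three_part 14  0.1332         2.60 6.73      NaN
#> 15 three_part 30  0.1881         3.06 9.35      NaN
```

Already at 200 replicates the pattern of interest is visible: OLS is
noticeably biased away from the covariate mean (x = 0 and 30) while the
three-part model is nearly unbiased everywhere; coverage requires
bootstrap SEs for the non-OLS models (`bootstrap = TRUE`, the default).
`build_default_grid()` returns the full 18-scenario study plan and
`run_study()` executes it.

A command-line wrapper over the same functions is installed with the
package (`exec/plossim`; subcommands `simulate`, `truth`, `run`,
`summarize`).

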