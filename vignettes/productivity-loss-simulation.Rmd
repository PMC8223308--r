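---
title: "Simulating and analysing zero- and max-inflated productivity loss outcomes"
author: "plossim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing zero- and max-inflated productivity loss outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plossim)
```

## The outcome and why ordinary models struggle with it

Work productivity loss over a fixed follow-up window (here 12 weeks, so a
maximum of `Max = 60` working days) is a bounded quantity with probability
mass concentrated at both ends of its range. A typical trial population
splits into three groups: subjects with *no* loss (often more than half the
sample), subjects with *some* loss strictly between 0 and the maximum, and
subjects who stopped working entirely and lost *all* 60 days. Ordinary
least squares ignores this three-part structure; a count model such as the
negative binomial acknowledges the skewness but not the two inflation
points. The question the package addresses by simulation is: when a trial
analyst wants the treatment effect at a chosen value of a single baseline
covariate, which of five commonly used regression strategies should they
trust?

## The data-generating mechanism

For treatment arm `arm` (0 or 1) and baseline covariate `x`, category
membership follows a multinomial logit with the total-loss category as
reference:

$$P_1(arm, x) = \frac{e^{\alpha_1 + \beta_1 arm + \gamma_1 x}}{e^{\alpha_1 + \beta_1 arm + \gamma_1 x} + e^{\alpha_2 + \beta_2 arm + \gamma_2 x} + 1},$$

similarly for $P_2$ (some loss), and $P_3 = 1 - P_1 - P_2$ (max loss). The
six coefficients are obtained in closed form from the two arms' category
probability triples at $x = 0$ (`derive_multinomial_params()`), so a
scenario is specified directly by interpretable quantities such as
"80% zero loss, 15% some loss, 5% max loss".

Outcomes in the middle category follow a negative binomial distribution
doubly truncated to $\{1, \dots, 59\}$. "Truncated at 0 and Max" is read
with *both* endpoints excluded, because the middle group is defined by
$0 < Y < Max$; the same convention puts the baseline covariate on
$\{0\} \cup \{1, \dots, 59\}$ (participants are working at baseline, so
$x = Max$ is excluded). The truncated distribution is parameterised by its
own mean and SD: `solve_truncated_nb()` finds the NB size and probability
parameters whose *truncated* moments match the targets, to within
$10^{-6}$ on both. The conditional mean shifts linearly in the covariate,

$$E(Y \mid 0 < Y < Max, arm, x) = E(Y \mid 0 < Y < Max, arm, 0) + a\,x,$$

with the NB success probability held at its $x = 0$ value and the size
parameter re-solved per covariate value. Holding $p$ fixed and solving the
size alone is the only parameterisation consistent with both a fixed
$p(arm, x) = p(arm, 0)$ and a linear mean shift; it reduces the per-$x$
work to a bracketed one-dimensional root find on the truncated mean
(tolerance $10^{-8}$).

The baseline covariate is zero-inflated: $x = 0$ with probability
$P = 0.30$, otherwise a draw from a doubly-truncated NB with non-zero mean
20 and SD 16 days. Its overall mean is therefore
$0.7 \times 20 = 14$ days, which is where "the covariate mean" evaluation
point $x = 14$ comes from.

### Numerical choices in the solver

The moment-matching solve is implemented as two *nested* deterministic 1-D
root finds rather than a 2-D Newton iteration: for a candidate success
probability $p$, the size $r$ is solved so the truncated mean matches (the
truncated mean is monotone increasing in $r$ at fixed $p$, so the bracket
$\log r \in [-25, 25]$ is safe), and $p$ is then solved on the logit scale
so the truncated SD matches, after a fixed 57-point grid scan locates a
sign change. Probability masses are normalised in log space so extreme
parameter pairs whose support mass underflows do not produce 0/0. Targets
with no attainable solution (a mean outside $(1, 59)$, or an SD no NB
shape reaches at that mean) produce an informative error rather than a
silent best effort.

### Sampling and reproducibility

Draws from the truncated distributions use inverse-CDF lookup on the
renormalised finite support — exact, rejection-free, and one uniform per
draw. Because the covariate is integer-valued, a scenario needs only 60
solved distributions per arm; `compile_scenario()` computes them once and
caches CDF tables, after which a replicate costs a few table lookups.

Each simulated arm consumes four fixed-length blocks of uniforms (covariate
zero-inflation, covariate value, category, middle value), drawn for every
subject whether used or not, so the RNG stream layout never depends on
earlier draws and `simulate_trial(scenario, seed)` is bit-reproducible. In
the replication loop, each replicate's seed is derived deterministically
from the master seed, a scenario index and the replicate number; bootstrap
resampling continues from the replicate's stream. Whether covariate and
category draws should share one stream is not dictated by anything
external; the ordering above is simply documented and fixed.

## The estimand and the five estimators

The target is the conditional treatment effect
$\theta(x) = E\{Y(1, x)\} - E\{Y(0, x)\}$, available analytically as

$$E\{Y(arm,x)\} = P_2(arm,x)\,\{E(Y \mid \text{mid}, arm, 0) + a x\} + P_3(arm,x) \cdot Max.$$

`true_mean()` uses the target truncated mean directly rather than
re-deriving it from the solved NB parameters, which match it by
construction. Default evaluation points are $x \in \{0, 14, 30\}$.

Each simulated dataset is analysed by five models, all regressing on
intercept, arm and $x$:

* **OLS** — the effect is the arm coefficient (constant in $x$), with its
  conventional model-based SE.
* **NB** — negative binomial GLM, log link, dispersion by joint ML;
  effect $e^{b_0+b_1+b_2 x} - e^{b_0+b_2 x}$.
* **ZTNB** — hurdle model: logistic regression for $P(Y=0)$, zero-truncated
  NB regression (log link on the untruncated mean) for the positives.
  The plug-in effect composes $(1 - \hat p_0(arm, x))$ with the mean of
  the *zero-truncated* distribution, $\hat\mu / (1 - \widehat{P}(0))$ —
  that is the conditional mean the hurdle model assigns to observed
  positives.
* **ZG** — the same hurdle structure with a log-link Gamma positive part.
  Both hurdle models treat the max-loss observations as ordinary
  positives: they model only zero versus non-zero.
* **Three-part** — multinomial logit for category membership (max loss as
  reference, mirroring the generating mechanism) plus a Beta regression
  on $y/60$ over the middle category, with logit mean link and a single
  scalar precision $\phi = \alpha + \beta$; effect
  $60\{\hat P_2(1,x)\hat\mu_B(1,x) + \hat P_3(1,x)\} - 60\{\cdot\}_{arm=0}$.

Links are the standard choices for each family (log for counts and Gamma,
logit for binary, multinomial and Beta means); nothing in the study design
pins them down, so they are documented here as the package's choice.

All five reduce to small fixed-design likelihood problems that the Monte
Carlo loop refits up to millions of times (5000 replicates × 1000
bootstrap resamples in the full design), so the package implements each as
a direct ML routine with analytic gradients (Newton iterations for the
logistic and multinomial parts, IRLS for the Gamma part, BFGS for the NB,
zero-truncated NB and Beta likelihoods). Beyond speed there is a
robustness reason: alternating-algorithm NB fitters can fail to converge
on zero-and-max-inflated outcomes where the direct joint likelihood
optimisation succeeds. The test suite cross-checks every engine against a
reference fitter (`stats::glm`, `MASS::glm.nb`, `nnet::multinom`) on
well-behaved data.

### Separation and other failures

With small arms and rare categories, the multinomial or logistic part may
have no finite ML optimum (quasi-complete separation). The package flags a
fit as separated when a categorical-part coefficient exceeds 15 in
absolute value, the Newton iteration hits its cap without the score
vanishing, or a category is perfectly predicted. This is an explicit
approximation to whatever rule a given software package applies
internally, so separation *counts* are comparable only qualitatively
across implementations. Flagged or non-converged fits contribute no
estimates; they are counted in a convergence ledger, per scenario and
model, together with a histogram of per-replicate bootstrap failure counts
(bins 0, 1–10, 11–100, 101–400, 401–700, 701–950, >950).

Degenerate inputs are treated as failures rather than special cases: a
dataset missing an outcome category in one arm is a precondition error for
the three-part model, a bootstrap resample losing a category is a failed
replicate, and a two-part fit on data with no zeros at all drives the
logistic intercept to $-\infty$ and is flagged as separation.

### Inference

SEs for all models except OLS come from a stratified bootstrap: subjects
are resampled with replacement *within* each arm (preserving the
randomised design), the model is refitted warm-started from the base fit,
and the SE is the SD of the successful replicate estimates; refit failures
are dropped and counted, and an SE based on fewer than half the resamples
is marked unreliable. Intervals are normal (Wald) by default,
$\hat\theta \pm 1.96\,SE$; the published tables report coverage without
stating the interval recipe, and normal-based is the conventional default
for simulation studies. Percentile bootstrap intervals are available as an
option (`ci_type = "percentile"`), without any claim about which recipe
the original analysis used.

## Performance measures

`summarize_performance()` implements the standard Monte Carlo measures:
bias, empirical SE (SD across replicates, $n-1$ denominator), model SE
(root-mean-square of the within-replicate SEs), MSE, coverage of nominal
95% intervals, and power against $\theta = 0$, each with its Monte Carlo
SE (e.g. $\sqrt{c(1-c)/n_{sim}}$ for coverage, empirical SE$/\sqrt{n_{sim}}$
for bias). Sizing the study follows the same logic in reverse:
`required_repetitions(4, 0.08)` — an assumed estimator SD of at most 4
days and an acceptable MCSE of bias of 0.08 — gives 2500 repetitions; the
default design doubles that to 5000, at which coverage near 95% carries an
MCSE of about 0.3 percentage points.

## The scenario grid and what passing tests show

`build_default_grid()` reproduces the full study design: three probability
configurations (arm 1 / arm 0 triples 80:15:5/60:30:10, 60:35:5/40:50:10,
50:40:10/30:55:15), two scale regimes (equal: middle-part SDs 13.34/14.63;
unequal: 12.00/16.00), and arm sizes 50, 100, 200, with middle-part means
15/20, $\gamma_1 = -0.02$, $\gamma_2 = -0.01$, $a = 0.15$. Two
applicability rules reflect what small samples can support: with 50 per
arm and 80% zero loss no comparison runs at all, and with 50 per arm and
5% max loss the three-part model is excluded.

The generator emulates the idealised trial the study design describes:
perfectly balanced arms, an integer-valued covariate independent of
treatment, no missingness, and a middle part that is exactly truncated-NB.
Real trial data violate most of these (continuous presenteeism fractions,
informative missingness, covariate imbalance), so agreement between the
estimators and the truth here demonstrates correctness of the machinery
and the comparative behaviour of the models under this mechanism — not
that any model is unbiased for real productivity-loss data.

Problem sizes used in the shipped checks are chosen to make Monte Carlo
noise small relative to the assertions: $10^6$ subjects for
generator-versus-truth consistency, the full 5000 replicates for measures
that need no bootstrap, 300 replicates × 200 resamples for
bootstrap-based coverage, and 1000 replicates per scenario for the
qualitative model orderings.

## Worked example

```{r example, eval = FALSE}
sc <- scenario_config(
  n_obs = 100,
  probs0 = c(0.60, 0.30, 0.10), probs1 = c(0.80, 0.15, 0.05),
  mid_sd0 = 14.63, mid_sd1 = 13.34,
  label = "80:15:5/60:30:10, equal scale")

true_effect(sc, c(0, 14, 30))
#> [1] -6.750000 -7.784932 -8.957279

d <- simulate_trial(sc, seed = 1)
effect_with_inference(d, "three_part", x_points = c(0, 14, 30),
                      B = 1000, seed = 2)

res <- run_scenario(sc, n_sim = 200, bootstrap = FALSE, master_seed = 1)
performance_table(res$estimates, true_effect_curve(sc))
```

## Known limitations

* Exactly one covariate, two arms, and an integer outcome support; the
  marginal (population-averaged) estimand is out of scope — the estimand
  is conditional on $x$ throughout.
* Zero-inflated mixture models (as opposed to hurdle models) are not
  implemented; the comparison treats the hurdle and three-part models as
  representatives of their respective classes.
* Separation counts depend on the detection rule and optimiser, so they
  reproduce qualitative patterns (rare at 200 per arm, most frequent with
  80% zeros at 100 per arm), not exact published counts.
* The bootstrap uses a fixed normal-interval recipe by default; coverage
  under the percentile option is computed but has no external anchor.
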