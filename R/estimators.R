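## Model kinds recognised throughout the package.
MODEL_KINDS <- c("ols", "nb", "ztnb", "zg", "three_part")

design_matrix <- function(data) {
  cbind(`(Intercept)` = 1, arm = data$arm, x = data$x)
}

new_ploss_fit <- function(kind, parts, converged, separated = FALSE,
                          max_loss = 60L) {
  structure(list(kind = kind, parts = parts, converged = converged,
                 separated = separated, max_loss = as.integer(max_loss)),
            class = "ploss_fit")
}

#' @export
print.ploss_fit <- function(x, ...) {
  cat(sprintf("Fitted model '%s' (%s%s)\n", x$kind,
              if (x$converged) "converged" else "NOT converged",
              if (x$separated) ", separation flagged" else ""))
  for (nm in names(x$parts)) {
    p <- x$parts[[nm]]
    if (!is.null(p$coef))
      cat(sprintf("  %-10s %s\n", nm,
                  paste(sprintf("%.4f", p$coef), collapse = "  ")))
  }
  invisible(x)
}

#' Fit one of the five regression strategies
#'
#' Fits the requested model to a simulated (or real) two-arm dataset with
#' columns `arm`, `x`, `y`. All models regress on an intercept, the arm
#' indicator and the covariate x.
#'
#' * `ols` - least squares on the raw outcome; the treatment effect is the
#'   arm coefficient, constant in x, with a conventional model-based SE.
#' * `nb` - negative binomial GLM with log link, dispersion by joint ML.
#' * `ztnb` - hurdle model: logistic regression for `P(Y = 0)` plus a
#'   zero-truncated negative binomial regression (log link on the
#'   untruncated mean) for the positives, which include the max-loss
#'   observations.
#' * `zg` - hurdle model with a log-link Gamma GLM positive part; shares
#'   the `ztnb` zero part by construction.
#' * `three_part` - multinomial logit for category membership
#'   (zero / some / max loss, max as reference) plus a Beta regression
#'   (logit mean link, scalar precision) for `y / max_loss` on the middle
#'   category.
#'
#' Convergence and separation diagnostics are carried on the returned
#' object; a fit with `converged = FALSE` yields no effect estimates.
#'
#' @param data Data frame with columns `arm` (0/1), `x`, `y`.
#' @param kind One of `"ols"`, `"nb"`, `"ztnb"`, `"zg"`, `"three_part"`.
#' @param max_loss Maximum attainable loss; defaults to `max(y)` rounded up
#'   to 60 when the data carry no attribute.
#' @return An object of class `"ploss_fit"`.
#' @export
fit_model <- function(data, kind = MODEL_KINDS, max_loss = 60L) {
  kind <- match.arg(kind)
  switch(kind,
         ols = fit_ols(data),
         nb = fit_nb(data),
         ztnb = fit_two_part(data, "zero_truncated_nb"),
         zg = fit_two_part(data, "gamma"),
         three_part = fit_three_part(data, max_loss = max_loss))
}

#' @rdname fit_model
#' @export
fit_ols <- function(data, ...) {
  X <- design_matrix(data)
  f <- ols_fit(X, data$y)
  new_ploss_fit("ols", list(mean = f), f$converged)
}

#' @rdname fit_model
#' @export
fit_nb <- function(data, ...) {
  stopifnot(all(data$y >= 0), all(data$y == round(data$y)))
  X <- design_matrix(data)
  f <- nb_ml(X, data$y)
  new_ploss_fit("nb", list(count = f), f$converged)
}

#' @rdname fit_model
#' @param positive_family Distribution of the positive part of the hurdle
#'   model: `"zero_truncated_nb"` or `"gamma"`.
#' @export
fit_two_part <- function(data,
                         positive_family = c("zero_truncated_nb", "gamma"),
                         ...) {
  positive_family <- match.arg(positive_family)
  X <- design_matrix(data)
  zero <- logit_fit(X, as.numeric(data$y == 0))
  pos <- data$y > 0
  if (!any(pos))
    return(new_ploss_fit(if (positive_family == "gamma") "zg" else "ztnb",
                         list(zero = zero), converged = FALSE,
                         separated = zero$separated))
  Xp <- X[pos, , drop = FALSE]
  yp <- data$y[pos]
  if (positive_family == "zero_truncated_nb") {
    stopifnot(all(yp == round(yp)))
    posf <- ztnb_ml(Xp, yp)
    kind <- "ztnb"
  } else {
    posf <- gamma_fit(Xp, yp)
    kind <- "zg"
  }
  new_ploss_fit(kind, list(zero = zero, positive = posf),
                converged = zero$converged && posf$converged,
                separated = zero$separated)
}

#' @rdname fit_model
#' @export
fit_three_part <- function(data, max_loss = 60L, ...) {
  K <- 1L + (data$y > 0) + (data$y >= max_loss)
  counts <- table(factor(data$arm, levels = 0:1), factor(K, levels = 1:3))
  if (any(counts == 0))
    stop("three-part model requires every arm to contain all three ",
         "outcome categories", call. = FALSE)
  X <- design_matrix(data)
  mn <- mlogit_ml(X, K)
  mid <- K == 2L
  bt <- beta_ml(X[mid, , drop = FALSE], data$y[mid] / max_loss)
  new_ploss_fit("three_part", list(multinomial = mn, beta = bt),
                converged = mn$converged && bt$converged,
                separated = mn$separated, max_loss = max_loss)
}

#' Quasi-complete separation diagnostic
#'
#' Flags fits whose categorical part shows evidence that the maximum
#' likelihood estimate does not exist: a coefficient exceeding 15 in
#' absolute value at the optimiser's stopping point, the iteration cap
#' being reached without the score vanishing, or a category that is
#' perfectly predicted on the observed data. The rule is an explicit,
#' documented approximation; separation counts in study output are
#' qualitative bookkeeping, not exactly reproducible quantities.
#'
#' @param data The dataset the model was fitted to (unused by the current
#'   rule, which reads stored diagnostics, but part of the stable
#'   signature).
#' @param fit A `"ploss_fit"` object.
#' @return Logical flag.
#' @export
detect_separation <- function(data, fit) {
  stopifnot(inherits(fit, "ploss_fit"))
  isTRUE(fit$separated)
}

#' Plug-in treatment-effect estimate at covariate values
#'
#' Evaluates the fitted model's implied estimate of
#' `theta(x) = E(Y | arm = 1, x) - E(Y | arm = 0, x)` by composing the
#' fitted parts, e.g. for hurdle models
#' `(1 - p0(arm, x)) * m(arm, x)` per arm with `m` the positive-part
#' conditional mean, and for the three-part model
#' `max_loss * (P_mid * mu_beta + P_max)` per arm.
#'
#' @param fit A converged `"ploss_fit"`.
#' @param x Covariate value(s).
#' @return Numeric vector of effect estimates (days).
#' @export
effect_at <- function(fit, x) {
  stopifnot(inherits(fit, "ploss_fit"), is.numeric(x), all(is.finite(x)))
  if (!fit$converged)
    stop("no effect estimates from a non-converged fit", call. = FALSE)
  lp <- function(coef, arm) coef[1] + coef[2] * arm + coef[3] * x
  switch(fit$kind,
    ols = rep(unname(fit$parts$mean$coef[2]), length(x)),
    nb = {
      cf <- fit$parts$count$coef
      exp(lp(cf, 1)) - exp(lp(cf, 0))
    },
    ztnb = {
      zc <- fit$parts$zero$coef
      pc <- fit$parts$positive$coef
      k <- fit$parts$positive$size
      m1 <- ztnb_cond_mean(exp(lp(pc, 1)), k)
      m0 <- ztnb_cond_mean(exp(lp(pc, 0)), k)
      (1 - stats::plogis(lp(zc, 1))) * m1 - (1 - stats::plogis(lp(zc, 0))) * m0
    },
    zg = {
      zc <- fit$parts$zero$coef
      pc <- fit$parts$positive$coef
      (1 - stats::plogis(lp(zc, 1))) * exp(lp(pc, 1)) -
        (1 - stats::plogis(lp(zc, 0))) * exp(lp(pc, 0))
    },
    three_part = {
      mn <- fit$parts$multinomial
      bc <- fit$parts$beta$coef
      eff_arm <- function(arm) {
        e1 <- exp(lp(mn$coef1, arm)); e2 <- exp(lp(mn$coef2, arm))
        den <- e1 + e2 + 1
        mu_b <- stats::plogis(lp(bc, arm))
        fit$max_loss * ((e2 / den) * mu_b + 1 / den)
      }
      eff_arm(1) - eff_arm(0)
    })
}

## Model-based SE of the effect; only OLS has one (the arm-coefficient SE,
## constant in x). Other models use the bootstrap.
model_se_at <- function(fit, x) {
  stopifnot(inherits(fit, "ploss_fit"))
  if (fit$kind != "ols")
    stop("model-based effect SEs are only available for OLS", call. = FALSE)
  rep(unname(fit$parts$mean$se[2]), length(x))
}

## Refit a model on a bootstrap resample, warm-started from the base fit.
## Returns effect estimates at x_points, or NULL for a failed/separated
## refit (counted by the caller).
refit_effects <- function(kind, Xb, yb, x_points, base, max_loss) {
  lp <- function(coef, arm) coef[1] + coef[2] * arm + coef[3] * x_points
  if (kind == "ols") {
    f <- ols_fit(Xb, yb)
    if (!f$converged) return(NULL)
    return(rep(unname(f$coef[2]), length(x_points)))
  }
  if (kind == "nb") {
    f <- nb_ml(Xb, yb, start = base$parts$count$par)
    if (!f$converged) return(NULL)
    return(exp(lp(f$coef, 1)) - exp(lp(f$coef, 0)))
  }
  if (kind %in% c("ztnb", "zg")) {
    zero <- logit_fit(Xb, as.numeric(yb == 0),
                      start = base$parts$zero$coef)
    if (!zero$converged || zero$separated) return(NULL)
    pos <- yb > 0
    if (!any(pos)) return(NULL)
    Xp <- Xb[pos, , drop = FALSE]; yp <- yb[pos]
    if (kind == "ztnb") {
      f <- ztnb_ml(Xp, yp, start = base$parts$positive$par)
      if (!f$converged) return(NULL)
      m1 <- ztnb_cond_mean(exp(lp(f$coef, 1)), f$size)
      m0 <- ztnb_cond_mean(exp(lp(f$coef, 0)), f$size)
    } else {
      f <- gamma_fit(Xp, yp, start = base$parts$positive$coef)
      if (!f$converged) return(NULL)
      m1 <- exp(lp(f$coef, 1)); m0 <- exp(lp(f$coef, 0))
    }
    return((1 - stats::plogis(lp(zero$coef, 1))) * m1 -
             (1 - stats::plogis(lp(zero$coef, 0))) * m0)
  }
  ## three_part
  K <- 1L + (yb > 0) + (yb >= max_loss)
  if (any(tabulate(K, 3L) == 0)) return(NULL)
  mn <- mlogit_ml(Xb, K, start = base$parts$multinomial$par)
  if (!mn$converged || mn$separated) return(NULL)
  mid <- K == 2L
  bt <- beta_ml(Xb[mid, , drop = FALSE], yb[mid] / max_loss,
                start = base$parts$beta$par)
  if (!bt$converged) return(NULL)
  eff_arm <- function(arm) {
    e1 <- exp(lp(mn$coef1, arm)); e2 <- exp(lp(mn$coef2, arm))
    den <- e1 + e2 + 1
    max_loss * ((e2 / den) * stats::plogis(lp(bt$coef, arm)) + 1 / den)
  }
  eff_arm(1) - eff_arm(0)
}

#' Stratified bootstrap standard errors of the effect estimate
#'
#' Resamples subjects with replacement within each arm (preserving the
#' randomised design), refits the model on each resample warm-started from
#' the base fit, and returns the per-x standard deviation of the successful
#' replicate estimates. Replicates whose refit fails to converge, shows
#' separation, or loses a required outcome category are dropped and
#' counted, exactly like any other failed replicate.
#'
#' @param data Data frame with columns `arm`, `x`, `y`.
#' @param kind Model kind; see [fit_model()].
#' @param x_points Covariate values at which the effect is evaluated.
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Optional seed for the resampling stream.
#' @param base Optional pre-computed base fit (avoids refitting).
#' @param max_loss Maximum attainable loss.
#' @return List with elements `se` (per-x SE), `n_failed` (failed
#'   replicates), `unreliable` (`TRUE` when more than half the replicates
#'   failed), and `draws` (the B x length(x_points) matrix of replicate
#'   estimates, failed rows `NA`).
#' @export
bootstrap_se <- function(data, kind = MODEL_KINDS, x_points = c(0, 14, 30),
                         B = 1000L, seed = NULL, base = NULL,
                         max_loss = 60L) {
  kind <- match.arg(kind)
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(base)) base <- fit_model(data, kind, max_loss = max_loss)
  if (!base$converged)
    stop("bootstrap requires a converged base fit", call. = FALSE)
  X <- design_matrix(data)
  y <- data$y
  i0 <- which(data$arm == 0); i1 <- which(data$arm == 1)
  draws <- matrix(NA_real_, B, length(x_points))
  for (b in seq_len(B)) {
    idx <- c(i0[sample.int(length(i0), replace = TRUE)],
             i1[sample.int(length(i1), replace = TRUE)])
    eff <- refit_effects(kind, X[idx, , drop = FALSE], y[idx],
                         x_points, base, max_loss)
    if (!is.null(eff)) draws[b, ] <- eff
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  se <- apply(draws[ok, , drop = FALSE], 2L, stats::sd)
  list(se = se, n_failed = n_failed, unreliable = n_failed > B / 2,
       draws = draws)
}

#' Effect estimates with inference at chosen covariate values
#'
#' Composes [fit_model()], [effect_at()] and either the model-based SE
#' (OLS) or [bootstrap_se()] (all other models) into per-x effect
#' estimates with normal (Wald) 95% intervals and a two-sided 5% test of
#' zero effect. Percentile bootstrap intervals are available as an option.
#'
#' @inheritParams bootstrap_se
#' @param ci_type `"normal"` for `theta_hat +/- 1.96 * SE`, or
#'   `"percentile"` for the 2.5/97.5 bootstrap percentiles (bootstrap
#'   models only).
#' @return A `data.frame` with one row per element of `x_points`: columns
#'   `model`, `x`, `theta_hat`, `se`, `ci_low`, `ci_high`, `reject_null`,
#'   `se_method`, `boot_failed`.
#' @export
effect_with_inference <- function(data, kind = MODEL_KINDS,
                                  x_points = c(0, 14, 30), B = 1000L,
                                  seed = NULL, ci_type = c("normal",
                                                           "percentile"),
                                  max_loss = 60L) {
  kind <- match.arg(kind)
  ci_type <- match.arg(ci_type)
  fit <- fit_model(data, kind, max_loss = max_loss)
  if (!fit$converged)
    stop("no effect estimates from a non-converged fit", call. = FALSE)
  theta <- effect_at(fit, x_points)
  boot_failed <- 0L
  if (kind == "ols") {
    se <- model_se_at(fit, x_points)
    se_method <- "model"
    lo <- theta - 1.96 * se; hi <- theta + 1.96 * se
  } else {
    bs <- bootstrap_se(data, kind, x_points, B = B, seed = seed,
                       base = fit, max_loss = max_loss)
    se <- bs$se
    se_method <- "bootstrap"
    boot_failed <- bs$n_failed
    if (ci_type == "percentile") {
      qs <- apply(bs$draws, 2L, stats::quantile,
                  probs = c(0.025, 0.975), na.rm = TRUE)
      lo <- qs[1L, ]; hi <- qs[2L, ]
    } else {
      lo <- theta - 1.96 * se; hi <- theta + 1.96 * se
    }
  }
  reject <- ifelse(se > 0, abs(theta / se) > 1.96, theta != 0)
  data.frame(model = kind, x = x_points, theta_hat = theta, se = se,
             ci_low = lo, ci_high = hi,
             reject_null = reject,
             se_method = se_method, boot_failed = boot_failed)
}
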