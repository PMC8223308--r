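#' Baseline covariate distribution parameters
#'
#' The covariate x is productivity loss at baseline: zero with probability
#' `p_zero`, otherwise an integer draw from a negative binomial distribution
#' doubly truncated to `{1, ..., max - 1}` whose truncated mean and SD are
#' `mu_x` and `sd_x`. The maximum is excluded because trial participants are
#' working at baseline.
#'
#' @param p_zero Probability of zero baseline loss, in `[0, 1)`.
#' @param mu_x,sd_x Mean and SD (days) of the non-zero part.
#' @param max Truncation bound (days).
#' @return An object of class `"covariate_params"`.
#' @export
covariate_params <- function(p_zero = 0.30, mu_x = 20, sd_x = 16, max = 60) {
  stopifnot(is.numeric(p_zero), length(p_zero) == 1L,
            p_zero >= 0, p_zero < 1,
            is.numeric(mu_x), mu_x > 0, is.numeric(sd_x), sd_x > 0,
            max == round(max), max > 2)
  structure(list(p_zero = p_zero, mu_x = mu_x, sd_x = sd_x,
                 max = as.integer(max)),
            class = "covariate_params")
}

#' Define one simulation scenario
#'
#' A scenario fully parameterises the data-generating mechanism for one
#' two-arm trial configuration: the category probability triples of both
#' arms at `x = 0`, the covariate coefficients of the category logits, the
#' conditional mean and SD of the middle ("some loss") part at `x = 0` per
#' arm, the per-unit covariate shift `slope_a` of that conditional mean,
#' the baseline covariate distribution, and the arm size.
#'
#' Probability triples are ordered `(P1, P2, P3)` = (zero loss, some loss,
#' max loss). The conditional middle-part mean at covariate x is
#' `mid_mean + slope_a * x` and must stay inside `(0, max_loss)` for every
#' attainable x.
#'
#' @param n_obs Subjects per arm.
#' @param probs0,probs1 Category probability triples at `x = 0` for arm 0
#'   (control) and arm 1 (treatment).
#' @param mid_mean0,mid_mean1 Middle-part conditional means at `x = 0`
#'   (days).
#' @param mid_sd0,mid_sd1 Corresponding conditional SDs (days).
#' @param gamma1,gamma2 Covariate coefficients of the category logits.
#' @param slope_a Per-unit-of-x shift of the middle-part conditional mean.
#' @param max_loss Maximum attainable loss (days).
#' @param covariate A [covariate_params()] object.
#' @param label Scenario name used in outputs.
#' @return An object of class `"scenario_config"`.
#' @export
#' @examples
#' sc <- scenario_config(
#'   n_obs = 100,
#'   probs0 = c(0.60, 0.30, 0.10), probs1 = c(0.80, 0.15, 0.05),
#'   mid_sd0 = 14.63, mid_sd1 = 13.34,
#'   label = "80:15:5/60:30:10, equal scale")
#' sc
scenario_config <- function(n_obs,
                            probs0, probs1,
                            mid_mean0 = 20, mid_mean1 = 15,
                            mid_sd0, mid_sd1,
                            gamma1 = -0.02, gamma2 = -0.01,
                            slope_a = 0.15,
                            max_loss = 60,
                            covariate = covariate_params(max = max_loss),
                            label = NULL) {
  stopifnot(length(n_obs) == 1L, n_obs == round(n_obs), n_obs >= 1,
            is.numeric(mid_mean0), is.numeric(mid_mean1),
            is.numeric(mid_sd0), mid_sd0 > 0,
            is.numeric(mid_sd1), mid_sd1 > 0,
            is.finite(gamma1), is.finite(gamma2), is.finite(slope_a),
            max_loss == round(max_loss), max_loss > 2,
            inherits(covariate, "covariate_params"))
  ## derive_multinomial_params validates the triples
  derive_multinomial_params(probs0, probs1, gamma1, gamma2)
  x_max <- covariate$max - 1L
  for (mm in c(mid_mean0, mid_mean1)) {
    rng <- mm + slope_a * c(0, x_max)
    if (any(rng <= 0) || any(rng >= max_loss))
      stop(sprintf(
        "middle-part mean %s + %s*x leaves (0, %d) over x in [0, %d]",
        format(mm), format(slope_a), max_loss, x_max), call. = FALSE)
  }
  if (is.null(label)) {
    fmt <- function(p) paste(round(100 * p), collapse = ":")
    label <- paste0(fmt(probs1), "/", fmt(probs0))
  }
  structure(list(
    n_obs = as.integer(n_obs),
    probs0 = probs0, probs1 = probs1,
    mid_mean0 = mid_mean0, mid_mean1 = mid_mean1,
    mid_sd0 = mid_sd0, mid_sd1 = mid_sd1,
    gamma1 = gamma1, gamma2 = gamma2,
    slope_a = slope_a,
    max_loss = as.integer(max_loss),
    covariate = covariate,
    label = label
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  cat(sprintf("  n per arm %d, max loss %d days\n", x$n_obs, x$max_loss))
  cat(sprintf("  P(zero, some, max) at x = 0: arm 1 (%.2f, %.2f, %.2f); arm 0 (%.2f, %.2f, %.2f)\n",
              x$probs1[1], x$probs1[2], x$probs1[3],
              x$probs0[1], x$probs0[2], x$probs0[3]))
  cat(sprintf("  middle part at x = 0: arm 1 mean %.2f sd %.2f; arm 0 mean %.2f sd %.2f; slope a = %.2f\n",
              x$mid_mean1, x$mid_sd1, x$mid_mean0, x$mid_sd0, x$slope_a))
  cat(sprintf("  covariate: P(x = 0) = %.2f, non-zero mean %.2f sd %.2f\n",
              x$covariate$p_zero, x$covariate$mu_x, x$covariate$sd_x))
  invisible(x)
}

#' Read or write a scenario as a YAML configuration file
#'
#' Scenarios round-trip through a flat YAML mapping so that simulation
#' configurations can be version-controlled and passed to the command-line
#' interface.
#'
#' @param scenario A [scenario_config()] object.
#' @param path File path.
#' @return `read_scenario()` returns a `"scenario_config"`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  x <- unclass(scenario)
  x$covariate <- unclass(x$covariate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  cov <- do.call(covariate_params, x$covariate)
  scenario_config(
    n_obs = x$n_obs,
    probs0 = as.numeric(x$probs0), probs1 = as.numeric(x$probs1),
    mid_mean0 = x$mid_mean0, mid_mean1 = x$mid_mean1,
    mid_sd0 = x$mid_sd0, mid_sd1 = x$mid_sd1,
    gamma1 = x$gamma1, gamma2 = x$gamma2,
    slope_a = x$slope_a, max_loss = x$max_loss,
    covariate = cov, label = x$label)
}
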