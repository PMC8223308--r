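#' Analytic mean outcome and true treatment effect
#'
#' `true_mean()` evaluates the plug-in expectation of the outcome at a
#' given arm and covariate value,
#' `E(Y | arm, x) = P2(arm, x) * (mid_mean(arm) + slope_a * x) +
#' P3(arm, x) * max_loss`, where the category probabilities come from the
#' scenario's multinomial logit. The middle-part term uses the target
#' truncated mean directly: the sampling distribution is solved to match it
#' exactly, so re-deriving it from the solved parameters would be
#' redundant.
#'
#' `true_effect()` is the simulation ground truth
#' `theta(x) = E(Y | arm = 1, x) - E(Y | arm = 0, x)`, the estimand every
#' fitted model targets.
#'
#' @param scenario A [scenario_config()] object.
#' @param arm Treatment arm, 0 or 1.
#' @param x Covariate value(s).
#' @return Numeric vector (days), one element per element of `x`.
#' @export
#' @examples
#' sc <- scenario_config(
#'   n_obs = 100,
#'   probs0 = c(0.60, 0.30, 0.10), probs1 = c(0.80, 0.15, 0.05),
#'   mid_sd0 = 14.63, mid_sd1 = 13.34)
#' true_mean(sc, arm = 1, x = 0)   # 0.15 * 15 + 0.05 * 60 = 5.25
#' true_effect(sc, x = c(0, 14, 30))
true_mean <- function(scenario, arm, x) {
  stopifnot(inherits(scenario, "scenario_config"),
            length(arm) == 1L, arm %in% c(0, 1),
            is.numeric(x), all(is.finite(x)))
  mp <- derive_multinomial_params(scenario$probs0, scenario$probs1,
                                  scenario$gamma1, scenario$gamma2)
  P <- category_probabilities(mp, arm, x)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L,
                                   dimnames = list(NULL, names(P)))
  mm <- if (arm == 1) scenario$mid_mean1 else scenario$mid_mean0
  unname(drop(P[, "mid"] * (mm + scenario$slope_a * x) +
                P[, "max"] * scenario$max_loss))
}

#' @rdname true_mean
#' @export
true_effect <- function(scenario, x) {
  true_mean(scenario, 1, x) - true_mean(scenario, 0, x)
}

#' True effect curve over a set of evaluation points
#'
#' @param scenario A [scenario_config()] object.
#' @param x_points Covariate values at which to evaluate the estimand.
#' @return A `data.frame` with columns `scenario`, `x`, `theta`.
#' @export
true_effect_curve <- function(scenario, x_points = c(0, 14, 30)) {
  data.frame(scenario = scenario$label, x = x_points,
             theta = true_effect(scenario, x_points))
}
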