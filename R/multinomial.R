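#' Multinomial-logit parameters for category membership
#'
#' The outcome of every subject falls in one of three categories: zero loss,
#' some loss (strictly between 0 and the maximum), or total loss. Category
#' membership follows a multinomial logit in treatment arm and the baseline
#' covariate x, with the total-loss category as the reference (linear
#' predictor 0):
#'
#' \deqn{P_1(arm, x) \propto \exp(\alpha_1 + \beta_1 arm + \gamma_1 x)}
#' \deqn{P_2(arm, x) \propto \exp(\alpha_2 + \beta_2 arm + \gamma_2 x)}
#' \deqn{P_3(arm, x) \propto 1}
#'
#' `derive_multinomial_params()` inverts these equations at `x = 0`: given
#' the two arms' category probability triples at baseline covariate zero and
#' the covariate coefficients, it returns the six logit coefficients. The
#' inversion is closed form, e.g. `alpha1 = log(P1(0,0) / P3(0,0))` and
#' `beta1 = log(P1(1,0) / P3(1,0)) - alpha1`.
#'
#' @param probs0,probs1 Length-3 probability triples `(P1, P2, P3)` at
#'   `x = 0` for arm 0 and arm 1; each strictly positive and summing to 1.
#' @param gamma1,gamma2 Covariate coefficients of the two non-reference
#'   linear predictors, passed through unchanged.
#' @param tol Tolerance for the sum-to-one check.
#' @return An object of class `"multinomial_params"` with fields `alpha1`,
#'   `beta1`, `gamma1`, `alpha2`, `beta2`, `gamma2`.
#' @seealso [category_probabilities()] for the forward map.
#' @export
#' @examples
#' mp <- derive_multinomial_params(c(0.60, 0.30, 0.10),
#'                                 c(0.80, 0.15, 0.05),
#'                                 gamma1 = -0.02, gamma2 = -0.01)
#' category_probabilities(mp, arm = 0, x = 0)  # recovers (0.60, 0.30, 0.10)
derive_multinomial_params <- function(probs0, probs1, gamma1, gamma2,
                                      tol = 1e-8) {
  check_triple <- function(p, name) {
    if (length(p) != 3L || !is.numeric(p) || any(!is.finite(p)) || any(p <= 0))
      stop(sprintf("%s must be three strictly positive probabilities", name),
           call. = FALSE)
    if (abs(sum(p) - 1) > tol)
      stop(sprintf("%s must sum to 1 (got %.10g)", name, sum(p)),
           call. = FALSE)
  }
  check_triple(probs0, "probs0")
  check_triple(probs1, "probs1")
  stopifnot(is.finite(gamma1), is.finite(gamma2))

  alpha1 <- log(probs0[1] / probs0[3])
  alpha2 <- log(probs0[2] / probs0[3])
  structure(list(
    alpha1 = alpha1,
    beta1  = log(probs1[1] / probs1[3]) - alpha1,
    gamma1 = gamma1,
    alpha2 = alpha2,
    beta2  = log(probs1[2] / probs1[3]) - alpha2,
    gamma2 = gamma2
  ), class = "multinomial_params")
}

#' @export
print.multinomial_params <- function(x, ...) {
  cat("Multinomial-logit category parameters (total loss = reference):\n")
  cat(sprintf("  zero loss : alpha1 = %8.4f  beta1 = %8.4f  gamma1 = %8.4f\n",
              x$alpha1, x$beta1, x$gamma1))
  cat(sprintf("  some loss : alpha2 = %8.4f  beta2 = %8.4f  gamma2 = %8.4f\n",
              x$alpha2, x$beta2, x$gamma2))
  invisible(x)
}

#' Category membership probabilities at given arm and covariate
#'
#' Forward evaluation of the three-category multinomial logit (see
#' [derive_multinomial_params()]). Computed through log-sum-exp so large
#' linear predictors cannot overflow.
#'
#' @param params A `"multinomial_params"` object.
#' @param arm Treatment arm, 0 or 1.
#' @param x Baseline covariate value(s); may be a vector.
#' @return For scalar `x`, a named numeric triple `(zero, mid, max)`;
#'   otherwise a matrix with one row per element of `x`.
#' @export
category_probabilities <- function(params, arm, x) {
  stopifnot(inherits(params, "multinomial_params"),
            length(arm) == 1L, arm %in% c(0, 1),
            is.numeric(x), all(is.finite(x)))
  eta1 <- params$alpha1 + params$beta1 * arm + params$gamma1 * x
  eta2 <- params$alpha2 + params$beta2 * arm + params$gamma2 * x
  m <- pmax(eta1, pmax(eta2, 0))
  e1 <- exp(eta1 - m); e2 <- exp(eta2 - m); e3 <- exp(-m)
  den <- e1 + e2 + e3
  out <- cbind(zero = e1 / den, mid = e2 / den, max = e3 / den)
  if (length(x) == 1L) out[1L, ] else out
}
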