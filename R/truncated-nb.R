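#' Doubly-truncated negative binomial distribution
#'
#' Container for a negative binomial distribution NB(r, p) restricted to the
#' open integer interval between `lower` and `upper`, i.e. with support
#' `{lower + 1, ..., upper - 1}`. Both endpoints are excluded: in the
#' productivity-loss setting the middle ("some loss") category is defined by
#' `0 < Y < Max`, and the baseline covariate by `0 < x < Max`.
#'
#' The parameterisation follows [stats::dnbinom()]: `r` is the size (number
#' of successes) and `p` the success probability, so the untruncated mean is
#' `r (1 - p) / p`.
#'
#' @param r Positive size parameter.
#' @param p Success probability in (0, 1).
#' @param lower,upper Integer truncation bounds, both excluded from the
#'   support; `upper - lower >= 2` is required so the support is non-empty.
#'
#' @return An object of class `"truncated_nb"`.
#' @seealso [truncated_nb_moments()], [solve_truncated_nb()]
#' @export
#' @examples
#' tnb <- truncated_nb(r = 0.82, p = 0.049, lower = 0, upper = 60)
#' truncated_nb_moments(tnb)
truncated_nb <- function(r, p, lower = 0L, upper) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(p), length(p) == 1L, p > 0, p < 1,
            length(lower) == 1L, length(upper) == 1L,
            lower == round(lower), upper == round(upper))
  if (upper - lower < 2)
    stop("empty support: need upper - lower >= 2", call. = FALSE)
  structure(list(r = r, p = p, lower = as.integer(lower),
                 upper = as.integer(upper)),
            class = "truncated_nb")
}

#' @export
print.truncated_nb <- function(x, ...) {
  m <- truncated_nb_moments(x)
  cat(sprintf("Doubly-truncated NB: r = %.6g, p = %.6g on {%d, ..., %d}\n",
              x$r, x$p, x$lower + 1L, x$upper - 1L))
  cat(sprintf("  truncated mean = %.4f, sd = %.4f\n", m[["mean"]], m[["sd"]]))
  invisible(x)
}

## Renormalised pmf over the support {lower+1, ..., upper-1}.
## Normalisation is done in log space so extreme (r, p) pairs whose mass on
## the support underflows do not produce 0/0.
tnb_pmf <- function(r, p, lower, upper) {
  support <- (lower + 1L):(upper - 1L)
  lw <- stats::dnbinom(support, size = r, prob = p, log = TRUE)
  mx <- max(lw)
  if (!is.finite(mx))
    stop("degenerate truncated NB: no probability mass on the support",
         call. = FALSE)
  w <- exp(lw - mx)
  w / sum(w)
}

#' Moments of a doubly-truncated negative binomial
#'
#' Exact mean and standard deviation of NB(r, p) conditioned on the finite
#' support `{lower + 1, ..., upper - 1}`, by direct summation over the
#' renormalised probability mass function.
#'
#' @param params A [truncated_nb()] object.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
truncated_nb_moments <- function(params) {
  stopifnot(inherits(params, "truncated_nb"))
  support <- (params$lower + 1L):(params$upper - 1L)
  w <- tnb_pmf(params$r, params$p, params$lower, params$upper)
  m <- sum(support * w)
  s <- sqrt(sum((support - m)^2 * w))
  c(mean = m, sd = s)
}

## Truncated mean as a function of log(r) at fixed p; monotone increasing in
## r, which makes the 1-D root find below safe to bracket.
tnb_mean_logr <- function(log_r, p, lower, upper) {
  support <- (lower + 1L):(upper - 1L)
  sum(support * tnb_pmf(exp(log_r), p, lower, upper))
}

## Solve r so that the truncated mean equals target_mean, holding p fixed.
## Returns NA (rather than erroring) when the target is outside the range
## attainable at this p, so the outer moment solver can skip such p.
solve_tnb_size <- function(target_mean, p, lower, upper,
                           tol = 1e-10, quiet = FALSE) {
  f <- function(lr) tnb_mean_logr(lr, p, lower, upper) - target_mean
  lo <- -25; hi <- 25
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    if (quiet) return(NA_real_)
    stop(sprintf(
      "no size parameter attains truncated mean %.4g at p = %.4g",
      target_mean, p), call. = FALSE)
  }
  exp(stats::uniroot(f, c(lo, hi), tol = tol)$root)
}

#' Match a doubly-truncated negative binomial to target moments
#'
#' Finds `(r, p)` such that NB(r, p) truncated to
#' `{lower + 1, ..., upper - 1}` has the requested mean and standard
#' deviation. This is the inverse operation of [truncated_nb_moments()] and
#' is what turns the mean/SD rows of a scenario table into samplable
#' distributions.
#'
#' The solve is two nested deterministic 1-D root finds: for each candidate
#' `p` the size `r` is chosen so the truncated mean matches (the truncated
#' mean is monotone in `r` at fixed `p`), and `p` is then chosen on the
#' logit scale so the truncated SD matches, after a fixed grid scan for a
#' sign change. Both moments are reproduced to within `tol`.
#'
#' @param target_mean,target_sd Required truncated mean and SD; the mean
#'   must lie strictly inside `(lower + 1, upper - 1)` and the SD must be
#'   positive and attainable on the support.
#' @param lower,upper Truncation bounds as in [truncated_nb()].
#' @param tol Absolute tolerance on both matched moments.
#' @return A [truncated_nb()] object.
#' @export
#' @examples
#' fit <- solve_truncated_nb(15, 13.34, lower = 0, upper = 60)
#' truncated_nb_moments(fit)  # recovers (15, 13.34)
solve_truncated_nb <- function(target_mean, target_sd, lower = 0L, upper,
                               tol = 1e-6) {
  stopifnot(is.numeric(target_mean), length(target_mean) == 1L,
            is.numeric(target_sd), length(target_sd) == 1L)
  if (upper - lower < 2)
    stop("empty support: need upper - lower >= 2", call. = FALSE)
  if (target_mean <= lower + 1 || target_mean >= upper - 1)
    stop(sprintf("target mean %.4g outside the attainable range (%d, %d)",
                 target_mean, lower + 1L, upper - 1L), call. = FALSE)
  if (target_sd <= 0)
    stop("target sd must be positive", call. = FALSE)

  sd_residual <- function(logit_p) {
    p <- stats::plogis(logit_p)
    r <- solve_tnb_size(target_mean, p, lower, upper, quiet = TRUE)
    if (is.na(r)) return(NA_real_)
    support <- (lower + 1L):(upper - 1L)
    w <- tnb_pmf(r, p, lower, upper)
    m <- sum(support * w)
    sqrt(sum((support - m)^2 * w)) - target_sd
  }

  grid <- seq(-14, 14, length.out = 57)
  vals <- vapply(grid, sd_residual, numeric(1))
  ok <- which(!is.na(vals))
  if (length(ok) < 2L)
    stop("no feasible (r, p): target mean unattainable across p",
         call. = FALSE)
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0L) {
    best <- ok[which.min(abs(vals[ok]))]
    stop(sprintf(
      "no (r, p) matches the target moments; best sd residual %.4g",
      vals[best]), call. = FALSE)
  }
  i <- ok[flip[1L]]; j <- ok[flip[1L] + 1L]
  root <- stats::uniroot(sd_residual, c(grid[i], grid[j]), tol = 1e-12)$root
  p <- stats::plogis(root)
  r <- solve_tnb_size(target_mean, p, lower, upper)

  out <- truncated_nb(r, p, lower, upper)
  m <- truncated_nb_moments(out)
  if (abs(m[["mean"]] - target_mean) > tol || abs(m[["sd"]] - target_sd) > tol)
    stop(sprintf(
      "moment match failed tolerance: residuals (%.3g, %.3g)",
      m[["mean"]] - target_mean, m[["sd"]] - target_sd), call. = FALSE)
  out
}

## Inverse-CDF sampler on the renormalised finite support (exact, no
## rejection). `u` is a vector of uniforms so callers control the RNG
## stream; returns integers in {lower+1, ..., upper-1}.
tnb_quantile <- function(u, cdf, lower) {
  lower + 1L + findInterval(u, cdf)
}
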