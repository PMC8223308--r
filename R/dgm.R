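#' Conditional mean of the middle part at covariate x
#'
#' The conditional mean of the outcome among subjects with some (but not
#' total) loss shifts linearly in the baseline covariate:
#' `E(Y | 0 < Y < Max, arm, x) = mid_mean(arm) + slope_a * x`. The success
#' probability of the underlying truncated negative binomial is held at its
#' `x = 0` value, and the size parameter is re-solved so the truncated mean
#' attains this target (see [compile_scenario()]).
#'
#' @param scenario A [scenario_config()] object.
#' @param arm Treatment arm, 0 or 1.
#' @param x Covariate value(s).
#' @return Numeric vector of conditional means (days).
#' @export
conditional_middle_mean <- function(scenario, arm, x) {
  stopifnot(inherits(scenario, "scenario_config"),
            length(arm) == 1L, arm %in% c(0, 1),
            is.numeric(x), all(is.finite(x)))
  mm <- if (arm == 1) scenario$mid_mean1 else scenario$mid_mean0
  out <- mm + scenario$slope_a * x
  if (any(out <= 0 | out >= scenario$max_loss))
    stop(sprintf("conditional middle mean outside (0, %d)",
                 scenario$max_loss), call. = FALSE)
  out
}

#' Precompute the sampling tables of a scenario
#'
#' Solving the truncated negative binomial parameters is the expensive part
#' of the data-generating mechanism, but for integer-valued covariates there
#' are only `max_loss` distinct covariate values per arm. This function
#' solves every required distribution once and attaches inverse-CDF lookup
#' tables to the scenario, so that [simulate_trial()] is a cheap table
#' lookup no matter how many replicates are drawn.
#'
#' Tables computed: the multinomial-logit coefficients; the covariate
#' distribution's truncated-NB CDF; and, per arm, one truncated-NB CDF row
#' per covariate value `x = 0, ..., max - 1` with the size parameter solved
#' so the truncated mean equals `mid_mean(arm) + slope_a * x` at the arm's
#' `x = 0` success probability.
#'
#' @param scenario A [scenario_config()] object.
#' @return The scenario with a `"tables"` attribute; idempotent.
#' @export
compile_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(attr(scenario, "tables"))) return(scenario)

  mp <- derive_multinomial_params(scenario$probs0, scenario$probs1,
                                  scenario$gamma1, scenario$gamma2)
  cov <- scenario$covariate
  cov_tnb <- solve_truncated_nb(cov$mu_x, cov$sd_x, 0L, cov$max)
  cov_cdf <- cumsum(tnb_pmf(cov_tnb$r, cov_tnb$p, 0L, cov$max))

  max_loss <- scenario$max_loss
  x_grid <- 0:(cov$max - 1L)
  arm_tables <- lapply(0:1, function(arm) {
    mm <- if (arm == 1) scenario$mid_mean1 else scenario$mid_mean0
    ss <- if (arm == 1) scenario$mid_sd1 else scenario$mid_sd0
    base <- solve_truncated_nb(mm, ss, 0L, max_loss)
    r_x <- vapply(x_grid, function(x)
      solve_tnb_size(mm + scenario$slope_a * x, base$p, 0L, max_loss),
      numeric(1))
    cdf <- t(vapply(r_x, function(r)
      cumsum(tnb_pmf(r, base$p, 0L, max_loss)),
      numeric(max_loss - 1L)))
    list(base = base, r_x = r_x, cdf = cdf)
  })

  attr(scenario, "tables") <- list(
    mp = mp, cov_tnb = cov_tnb, cov_cdf = cov_cdf,
    arm = arm_tables, x_grid = x_grid)
  scenario
}

#' Draw baseline covariate values
#'
#' Each subject's baseline loss is 0 with probability `p_zero` and
#' otherwise an integer draw from the doubly-truncated negative binomial
#' solved from `(mu_x, sd_x)` on `{1, ..., max - 1}`. Two blocks of `n`
#' uniforms are consumed from the current RNG stream, in order: the
#' zero-inflation Bernoulli draws, then the truncated-NB inverse-CDF draws
#' (the latter are drawn for every subject and ignored for those set to
#' zero, which keeps the stream layout fixed).
#'
#' @param cov A [covariate_params()] object.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_covariates <- function(cov, n) {
  stopifnot(inherits(cov, "covariate_params"), n >= 1)
  tnb <- solve_truncated_nb(cov$mu_x, cov$sd_x, 0L, cov$max)
  cdf <- cumsum(tnb_pmf(tnb$r, tnb$p, 0L, cov$max))
  zero <- stats::runif(n) < cov$p_zero
  val <- tnb_quantile(stats::runif(n), cdf, 0L)
  ifelse(zero, 0L, val)
}

#' Simulate one two-arm trial dataset
#'
#' Draws `n_obs` subjects per arm from the full data-generating mechanism.
#' Per arm (arm 0 first), four blocks of `n_obs` uniforms are consumed from
#' the RNG stream in a fixed, documented order: covariate zero-inflation,
#' covariate value, category membership, middle-part value. Blocks are drawn
#' for every subject regardless of whether the draw is used, so the stream
#' layout does not depend on earlier draws and runs are bit-reproducible
#' under a fixed seed.
#'
#' Each subject's outcome is 0 in the zero-loss category, `max_loss` in the
#' total-loss category, and a doubly-truncated negative binomial draw whose
#' conditional mean is `mid_mean(arm) + slope_a * x` otherwise.
#'
#' @param scenario A [scenario_config()] object, compiled or not (see
#'   [compile_scenario()]; compiling once up front is much faster when
#'   simulating many replicates).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the dataset is a pure function of `(scenario, seed)`.
#' @return A `data.frame` of class `"trial_data"` with columns `arm`
#'   (0/1), `x` and `y` (days), `2 * n_obs` rows, and the scenario label as
#'   attribute `"scenario"`.
#' @export
#' @examples
#' sc <- scenario_config(
#'   n_obs = 100,
#'   probs0 = c(0.60, 0.30, 0.10), probs1 = c(0.80, 0.15, 0.05),
#'   mid_sd0 = 14.63, mid_sd1 = 13.34)
#' head(simulate_trial(sc, seed = 1))
simulate_trial <- function(scenario, seed = NULL) {
  scenario <- compile_scenario(scenario)
  tab <- attr(scenario, "tables")
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_obs
  cov <- scenario$covariate
  parts <- lapply(0:1, function(arm) {
    zero_x <- stats::runif(n) < cov$p_zero
    xv <- tnb_quantile(stats::runif(n), tab$cov_cdf, 0L)
    x <- ifelse(zero_x, 0L, xv)
    P <- category_probabilities(tab$mp, arm, x)
    u <- stats::runif(n)
    K <- 1L + (u >= P[, "zero"]) + (u >= P[, "zero"] + P[, "mid"])
    um <- stats::runif(n)
    y <- numeric(n)
    mid <- which(K == 2L)
    if (length(mid)) {
      cdf <- tab$arm[[arm + 1L]]$cdf[x[mid] + 1L, , drop = FALSE]
      y[mid] <- 1L + rowSums(um[mid] > cdf)
    }
    y[K == 3L] <- scenario$max_loss
    data.frame(arm = arm, x = as.integer(x), y = as.numeric(y))
  })
  out <- rbind(parts[[1L]], parts[[2L]])
  rownames(out) <- NULL
  class(out) <- c("trial_data", "data.frame")
  attr(out, "scenario") <- scenario$label
  attr(out, "n_obs") <- n
  out
}

#' Export or import a simulated trial dataset as CSV
#'
#' @param data A `"trial_data"` data frame.
#' @param path File path.
#' @return `read_trial_csv()` returns a `"trial_data"` data frame;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("arm", "x", "y") %in% names(data)))
  utils::write.csv(data[, c("arm", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("arm", "x", "y") %in% names(out)))
  class(out) <- c("trial_data", "data.frame")
  out
}
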