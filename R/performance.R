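#' Monte Carlo performance measures for one estimator at one x
#'
#' Aggregates per-replicate effect estimates into the six standard
#' simulation-study performance measures, each with its Monte Carlo
#' standard error:
#'
#' * bias: `mean(theta_hat) - theta`; MCSE `empirical SE / sqrt(n)`.
#' * empirical SE: `sd(theta_hat)` (n - 1 denominator); MCSE
#'   `empSE / sqrt(2 (n - 1))`.
#' * model SE: `sqrt(mean(se^2))` (root-mean-square convention); MCSE
#'   `sqrt(var(se^2) / (4 n modSE^2))`.
#' * MSE: `mean((theta_hat - theta)^2)`; MCSE
#'   `sqrt(var((theta_hat - theta)^2) / n)`.
#' * coverage: fraction of intervals containing `theta`; MCSE
#'   `sqrt(c (1 - c) / n)`.
#' * power: fraction of replicates rejecting zero effect; same binomial
#'   MCSE form.
#'
#' Replicates with missing entries (non-converged or separated fits that
#' contributed no estimate) must be removed before calling; `n_used`
#' records how many contributed.
#'
#' @param estimates Data frame of per-replicate results with columns
#'   `theta_hat`, `se`, `ci_low`, `ci_high`, `reject_null`.
#' @param theta_true True value of the estimand.
#' @return A one-row `data.frame` with the six measures and their MCSEs.
#' @export
summarize_performance <- function(estimates, theta_true) {
  need <- c("theta_hat", "se", "ci_low", "ci_high", "reject_null")
  stopifnot(is.data.frame(estimates), all(need %in% names(estimates)),
            length(theta_true) == 1L, is.finite(theta_true))
  th <- estimates$theta_hat
  n <- length(th)
  if (n < 2L)
    stop("at least 2 contributing replicates required", call. = FALSE)
  emp_se <- stats::sd(th)
  bias <- mean(th) - theta_true
  err2 <- (th - theta_true)^2
  mse <- mean(err2)
  ## SE-based measures use only replicates that carry an SE (runs without
  ## bootstrap inference report NA SEs for the non-OLS models)
  se2 <- estimates$se[!is.na(estimates$se)]^2
  n_se <- length(se2)
  mod_se <- if (n_se) sqrt(mean(se2)) else NA_real_
  mod_se_mcse <- if (n_se > 1 && mod_se > 0)
    sqrt(stats::var(se2) / (4 * n_se * mod_se^2)) else NA_real_
  covered <- estimates$ci_low <= theta_true &
    theta_true <= estimates$ci_high
  cover <- mean(covered, na.rm = TRUE)
  pow <- mean(estimates$reject_null, na.rm = TRUE)
  data.frame(
    n_used = n,
    bias = bias,            bias_mcse = emp_se / sqrt(n),
    empirical_se = emp_se,  empirical_se_mcse = emp_se / sqrt(2 * (n - 1)),
    model_se = mod_se,      model_se_mcse = mod_se_mcse,
    mse = mse,              mse_mcse = sqrt(stats::var(err2) / n),
    coverage = cover,       coverage_mcse = sqrt(cover * (1 - cover) / n),
    power = pow,            power_mcse = sqrt(pow * (1 - pow) / n))
}

#' Repetitions needed for a target Monte Carlo SE of bias
#'
#' The Monte Carlo SE of bias is `SD(theta_hat) / sqrt(n_sim)`, so hitting
#' a target requires `ceiling((sd_theta / target)^2)` repetitions. With an
#' assumed estimator SD of 4 days and an acceptable MCSE of 0.08, this
#' gives 2500 repetitions.
#'
#' @param sd_theta Assumed SD of the effect estimator across replicates.
#' @param target_mcse_bias Acceptable Monte Carlo SE of bias.
#' @return Integer number of repetitions.
#' @export
#' @examples
#' required_repetitions(4, 0.08)  # 2500
required_repetitions <- function(sd_theta, target_mcse_bias) {
  stopifnot(sd_theta > 0, target_mcse_bias > 0)
  as.integer(ceiling((sd_theta / target_mcse_bias)^2))
}

#' Monte Carlo SE of a coverage (or power) estimate
#'
#' @param p The coverage or power proportion.
#' @param n_sim Number of simulation replicates.
#' @return `sqrt(p * (1 - p) / n_sim)`.
#' @export
#' @examples
#' mcse_proportion(0.95, 5000)  # ~0.003, i.e. 0.3 percentage points
mcse_proportion <- function(p, n_sim) {
  stopifnot(p >= 0, p <= 1, n_sim >= 1)
  sqrt(p * (1 - p) / n_sim)
}

#' Performance table across scenarios, models and evaluation points
#'
#' Summarises a long data frame of per-replicate effect estimates (as
#' produced by [run_scenario()]) into one row per
#' `(scenario, model, x)` cell, attaching the true estimand from `truth`.
#'
#' @param estimates Long data frame with columns `scenario`, `model`, `x`,
#'   `theta_hat`, `se`, `ci_low`, `ci_high`, `reject_null`.
#' @param truth Data frame with columns `scenario`, `x`, `theta` (see
#'   [true_effect_curve()]).
#' @return A `data.frame` of class `"performance_table"`.
#' @export
performance_table <- function(estimates, truth) {
  stopifnot(all(c("scenario", "model", "x") %in% names(estimates)),
            all(c("scenario", "x", "theta") %in% names(truth)))
  keys <- unique(estimates[, c("scenario", "model", "x")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- estimates[estimates$scenario == k$scenario &
                       estimates$model == k$model &
                       estimates$x == k$x, ]
    sub <- sub[is.finite(sub$theta_hat), ]
    th <- truth$theta[truth$scenario == k$scenario & truth$x == k$x]
    if (length(th) != 1L)
      stop(sprintf("no unique truth for scenario '%s' at x = %s",
                   k$scenario, format(k$x)), call. = FALSE)
    cbind(k, theta_true = th, summarize_performance(sub, th))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Write one CSV per performance measure
#'
#' Each file has one row per scenario and one column per model, cells
#' formatted `"estimate (MCSE)"`, mirroring the usual presentation of
#' simulation-study result tables.
#'
#' @param perf A [performance_table()] result.
#' @param dir Output directory (created if needed).
#' @param measures Which measures to write.
#' @return Invisibly, the paths written.
#' @export
write_performance_tables <- function(perf, dir,
                                     measures = c("bias", "coverage",
                                                  "power", "empirical_se",
                                                  "model_se", "mse")) {
  stopifnot(inherits(perf, "performance_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- unique(perf$model)
  paths <- character(0)
  for (m in measures) {
    cells <- sprintf("%.4g (%.4g)", perf[[m]], perf[[paste0(m, "_mcse")]])
    wide <- stats::reshape(
      data.frame(scenario = perf$scenario, x = perf$x, model = perf$model,
                 value = cells, stringsAsFactors = FALSE),
      idvar = c("scenario", "x"), timevar = "model", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    p <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(wide, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
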