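## Internal maximum-likelihood engines.
##
## All five regression strategies reduce to small fixed-design problems
## (design matrix [1, arm, x]) that are refitted millions of times across
## Monte Carlo replicates and bootstrap resamples, so each family gets a
## direct ML routine with analytic gradients instead of a generic model
## frame pipeline. Each routine is cross-checked in the test suite against
## the corresponding reference fitter (stats::glm, MASS::glm.nb,
## nnet::multinom) on well-behaved data.

BIG_NEGLL <- 1e10

## ---- ordinary least squares -------------------------------------------

ols_fit <- function(X, y) {
  ## aliased columns (e.g. a constant covariate) are dropped, keeping the
  ## arm contrast estimable whenever possible
  coef <- unname(qr.coef(qr(X), y))
  aliased <- is.na(coef)
  if (isTRUE(aliased[2L]))
    return(list(coef = rep(NA_real_, ncol(X)), converged = FALSE))
  Xk <- X[, !aliased, drop = FALSE]
  qk <- qr(Xk)
  ck <- qr.coef(qk, y)
  res <- y - drop(Xk %*% ck)
  df <- length(y) - ncol(Xk)
  if (df <= 0)
    return(list(coef = rep(NA_real_, ncol(X)), converged = FALSE))
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qk))
  se <- rep(NA_real_, ncol(X))
  se[!aliased] <- sqrt(sigma2 * diag(XtXinv))
  coef[aliased] <- 0
  coef[!aliased] <- ck
  list(coef = coef, se = se, sigma2 = sigma2, df = df, converged = TRUE)
}

## ---- logistic regression (Newton / IRLS) ------------------------------

logit_fit <- function(X, yb, start = NULL, maxit = 30L, tol = 1e-9) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- crossprod(X, yb - mu)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 40) break   # diverging: separation
  }
  mu <- stats::plogis(drop(X %*% beta))
  perfect <- all(abs(yb - mu) < 1e-6)
  separated <- !converged || max(abs(beta)) > 15 || perfect
  list(coef = beta, converged = converged, separated = separated)
}

## ---- Gamma GLM with log link (IRLS) -----------------------------------
## Under the log link the Gamma IRLS weights are identically 1, so each
## update is an unweighted least-squares solve with a fixed design.

gamma_fit <- function(X, y, start = NULL, maxit = 50L, tol = 1e-10) {
  if (any(y <= 0)) return(list(coef = rep(NA_real_, ncol(X)),
                               converged = FALSE))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    return(list(coef = rep(NA_real_, ncol(X)), converged = FALSE))
  beta <- if (is.null(start)) unname(qr.coef(qx, log(y))) else start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (any(abs(eta) > 50)) break
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- qr.coef(qx, z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new
      converged <- TRUE; break }
    beta <- beta_new
  }
  list(coef = unname(beta), converged = converged)
}

## ---- negative binomial GLM (joint ML over coefficients and log size) --

nb_negll <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(BIG_NEGLL)
  k <- exp(par[np]); mu <- drop(exp(X %*% par[-np]))
  if (!all(is.finite(mu)) || any(mu <= 0)) return(BIG_NEGLL)
  ll <- sum(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
              k * log(k / (k + mu)) +
              ifelse(y > 0, y * log(mu / (k + mu)), 0))
  if (!is.finite(ll)) return(BIG_NEGLL)
  -ll
}

nb_grad <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(numeric(np))
  k <- exp(par[np]); mu <- drop(exp(X %*% par[-np]))
  gb <- drop(crossprod(X, k * (y - mu) / (k + mu)))
  gk <- k * sum(digamma(y + k) - digamma(k) + log(k / (k + mu)) +
                  (mu - y) / (k + mu))
  -c(gb, gk)
}

nb_ml <- function(X, y, start = NULL) {
  if (all(y == 0)) return(list(coef = rep(NA_real_, ncol(X)),
                               size = NA_real_, converged = FALSE))
  if (is.null(start))
    start <- c(unname(qr.coef(qr(X), log(y + 0.5))), 0)
  o <- stats::optim(start, nb_negll, nb_grad, X = X, y = y,
                    method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  np <- length(o$par)
  list(coef = unname(o$par[-np]), size = unname(exp(o$par[np])),
       par = unname(o$par),
       negll = o$value,
       converged = o$convergence == 0 && o$value < BIG_NEGLL)
}

## ---- zero-truncated negative binomial (hurdle positive part) ----------
## Log link on the *untruncated* NB mean mu; the likelihood conditions on
## y >= 1 by dividing out 1 - P(0).

ztnb_negll <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(BIG_NEGLL)
  k <- exp(par[np]); mu <- drop(exp(X %*% par[-np]))
  if (!all(is.finite(mu))) return(BIG_NEGLL)
  lp0 <- k * (log(k) - log(k + mu))
  ll <- sum(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
              k * log(k / (k + mu)) + y * log(mu / (k + mu)) -
              log1p(-exp(lp0)))
  if (!is.finite(ll)) return(BIG_NEGLL)
  -ll
}

ztnb_grad <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(numeric(np))
  k <- exp(par[np]); mu <- drop(exp(X %*% par[-np]))
  lp0 <- k * (log(k) - log(k + mu))
  p0 <- exp(lp0); w <- p0 / (1 - p0)
  g_eta <- k * (y - mu) / (k + mu) - w * k * mu / (k + mu)
  gb <- drop(crossprod(X, g_eta))
  dlp0_dlk <- k * (log(k / (k + mu)) + mu / (k + mu))
  gk <- k * sum(digamma(y + k) - digamma(k) + log(k / (k + mu)) +
                  (mu - y) / (k + mu)) - sum(w * dlp0_dlk)
  -c(gb, gk)
}

ztnb_ml <- function(X, y, start = NULL) {
  if (is.null(start))
    start <- c(unname(qr.coef(qr(X), log(y))), 0)
  o <- stats::optim(start, ztnb_negll, ztnb_grad, X = X, y = y,
                    method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  np <- length(o$par)
  list(coef = unname(o$par[-np]), size = unname(exp(o$par[np])),
       par = unname(o$par),
       negll = o$value,
       converged = o$convergence == 0 && o$value < BIG_NEGLL)
}

## Mean of the zero-truncated distribution implied by untruncated mean mu
## and size k: E(Y | Y > 0) = mu / (1 - P(0)).
ztnb_cond_mean <- function(mu, k) {
  p0 <- exp(k * (log(k) - log(k + mu)))
  mu / (1 - p0)
}

## ---- Beta regression (logit mean link, scalar precision) --------------

beta_negll <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(BIG_NEGLL)
  mu <- stats::plogis(drop(X %*% par[-np])); phi <- exp(par[np])
  a <- mu * phi; b <- (1 - mu) * phi
  if (any(a <= 0) || any(b <= 0)) return(BIG_NEGLL)
  ll <- sum(lgamma(phi) - lgamma(a) - lgamma(b) +
              (a - 1) * log(y) + (b - 1) * log1p(-y))
  if (!is.finite(ll)) return(BIG_NEGLL)
  -ll
}

beta_grad <- function(par, X, y) {
  np <- length(par)
  if (any(abs(par) > 50)) return(numeric(np))
  mu <- stats::plogis(drop(X %*% par[-np])); phi <- exp(par[np])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                      (1 - mu) * digamma((1 - mu) * phi) +
                      mu * log(y) + (1 - mu) * log1p(-y))
  -c(gb, gphi)
}

beta_ml <- function(X, y, start = NULL) {
  if (is.null(start)) {
    mbar <- mean(y); v <- stats::var(y)
    phi0 <- max(mbar * (1 - mbar) / max(v, 1e-6) - 1, 0.5)
    start <- c(stats::qlogis(mbar), numeric(ncol(X) - 1L), log(phi0))
  }
  o <- stats::optim(start, beta_negll, beta_grad, X = X, y = y,
                    method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  np <- length(o$par)
  list(coef = unname(o$par[-np]), phi = unname(exp(o$par[np])),
       par = unname(o$par),
       negll = o$value,
       converged = o$convergence == 0 && o$value < BIG_NEGLL)
}

## ---- three-category multinomial logit (Newton), reference = category 3 -
## K takes values 1 (zero loss), 2 (some loss), 3 (max loss, reference),
## mirroring the data-generating parameterisation so recovered coefficients
## are directly comparable with derive_multinomial_params() output.

mlogit_ml <- function(X, K, start = NULL, maxit = 60L, tol = 1e-8) {
  p <- ncol(X)
  par <- if (is.null(start)) numeric(2L * p) else start
  Y1 <- K == 1L; Y2 <- K == 2L
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta1 <- drop(X %*% par[1:p]); eta2 <- drop(X %*% par[(p + 1):(2 * p)])
    m <- pmax(eta1, pmax(eta2, 0))
    e1 <- exp(eta1 - m); e2 <- exp(eta2 - m); e3 <- exp(-m)
    den <- e1 + e2 + e3
    P1 <- e1 / den; P2 <- e2 / den
    score <- c(crossprod(X, Y1 - P1), crossprod(X, Y2 - P2))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    H <- matrix(0, 2 * p, 2 * p)
    H[1:p, 1:p] <- crossprod(X, X * (P1 * (1 - P1)))
    H[(p + 1):(2 * p), (p + 1):(2 * p)] <- crossprod(X, X * (P2 * (1 - P2)))
    H[1:p, (p + 1):(2 * p)] <- crossprod(X, X * (-P1 * P2))
    H[(p + 1):(2 * p), 1:p] <- t(H[1:p, (p + 1):(2 * p)])
    step <- tryCatch(solve(H + diag(1e-10, 2 * p), score),
                     error = function(e) NULL)
    if (is.null(step)) break
    ## dampen huge steps to keep early iterations stable
    sm <- max(abs(step))
    if (sm > 5) step <- step * (5 / sm)
    par <- par + drop(step)
    if (max(abs(par)) > 40) break   # diverging: separation
  }
  eta1 <- drop(X %*% par[1:p]); eta2 <- drop(X %*% par[(p + 1):(2 * p)])
  m <- pmax(eta1, pmax(eta2, 0))
  e1 <- exp(eta1 - m); e2 <- exp(eta2 - m); e3 <- exp(-m)
  den <- e1 + e2 + e3
  P <- cbind(e1 / den, e2 / den, e3 / den)
  Pobs <- P[cbind(seq_along(K), K)]
  perfect <- any(vapply(1:3, function(j)
    any(K == j) && all(Pobs[K == j] > 1 - 1e-6), logical(1)))
  separated <- !converged || max(abs(par)) > 15 || perfect
  list(par = par, coef1 = par[1:p], coef2 = par[(p + 1):(2 * p)],
       converged = converged, separated = separated, iter = iter)
}
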