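# Two-part hurdle model for zero-inflated, over-dispersed habitat-use
# counts, from first principles. The zero part is a Bernoulli
# presence/absence process with a logit link; the count part models the
# positive counts with a zero-truncated Poisson or negative binomial with a
# log link. The two parts factorise, so they are maximised separately by
# quasi-Newton optimisation from deterministic starts, with standard errors
# from the observed information (finite-difference Hessian).

# log pmf of the zero-truncated count families at y >= 1
.ztrunc_logpmf <- function(y, mu, family, theta = NULL) {
  if (family == "poisson") {
    y * log(mu) - mu - lgamma(y + 1) - log1p(-exp(-mu))
  } else {
    lp0 <- theta * (log(theta) - log(theta + mu)) # log P(Y = 0)
    dnbinom(y, mu = mu, size = theta, log = TRUE) - log1p(-exp(lp0))
  }
}

#' Hurdle-model log-likelihood
#'
#' Sum over observations of the Bernoulli presence log-likelihood plus, for
#' positive counts, the log zero-truncated count pmf (log-link mean).
#'
#' @param params List with `zero = c(intercept, slope)`,
#'   `count = c(intercept, slope)`, and for the negative binomial family
#'   `log_theta`.
#' @param counts Non-negative integer response.
#' @param covariate Numeric covariate (e.g. cell SST).
#' @param family `"poisson"` or `"negbin"` (zero-truncated).
#' @return Log-likelihood (scalar).
#' @export
hurdle_loglik <- function(params, counts, covariate,
                          family = c("negbin", "poisson")) {
  family <- match.arg(family)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  eta_z <- params$zero[1] + params$zero[2] * covariate
  pos <- counts > 0
  # Bernoulli(presence | logit^-1(eta)): use plogis log form for stability
  ll <- sum(plogis(eta_z[pos], log.p = TRUE)) +
    sum(plogis(eta_z[!pos], log.p = TRUE, lower.tail = FALSE))
  if (any(pos)) {
    mu <- exp(params$count[1] + params$count[2] * covariate[pos])
    theta <- if (family == "negbin") exp(params$log_theta) else NULL
    ll <- ll + sum(.ztrunc_logpmf(counts[pos], mu, family, theta))
  }
  ll
}

# quasi-Newton maximisation (analytic gradients where supplied) from
# several deterministic starts
.ml_optim <- function(nll, starts, gr = NULL) {
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, gr = gr, method = "BFGS", hessian = TRUE,
        control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("hurdle optimisation failed from all starts")
  best
}

#' Fit the two-part hurdle model by maximum likelihood
#'
#' @param counts Non-negative integer response (per-cell location counts).
#' @param covariate Numeric covariate (per-cell SST or SST anomaly).
#' @param family Count family: zero-truncated `"negbin"` (default; habitat
#'   counts are typically over-dispersed) or `"poisson"`.
#' @return A list of class `hurdle_fit` with `zero` and `count` coefficient
#'   tibbles (`term, estimate, se, z_value, p_value`), `theta` (negbin
#'   dispersion), `loglik`, `aic`, `n`, `family`.
#' @export
hurdle_fit <- function(counts, covariate, family = c("negbin", "poisson")) {
  family <- match.arg(family)
  keep <- complete.cases(counts, covariate)
  counts <- counts[keep]
  covariate <- covariate[keep]
  pos <- counts > 0
  if (!any(pos) || all(pos)) abort("need both zero and positive counts")

  # --- zero part: Bernoulli logit MLE
  z <- as.numeric(pos)
  nll_zero <- function(p) {
    eta <- p[1] + p[2] * covariate
    -sum(z * plogis(eta, log.p = TRUE) +
      (1 - z) * plogis(eta, log.p = TRUE, lower.tail = FALSE))
  }
  gr_zero <- function(p) {
    r <- z - plogis(p[1] + p[2] * covariate)
    -c(sum(r), sum(r * covariate))
  }
  p0 <- stats::qlogis(mean(z))
  oz <- .ml_optim(nll_zero, list(c(0, 0), c(p0, 0), c(p0, -0.1)), gr = gr_zero)
  se_z <- sqrt(diag(solve(oz$hessian)))
  if (any(abs(oz$par[1] + oz$par[2] * range(covariate)) > 30)) {
    warn("possible separation in the zero part; estimates unreliable")
  }

  # --- count part: zero-truncated family on positives only
  yp <- counts[pos]
  xp <- covariate[pos]
  np <- if (family == "negbin") 3 else 2
  nll_count <- function(p) {
    mu <- exp(p[1] + p[2] * xp)
    th <- if (family == "negbin") exp(p[3]) else NULL
    v <- -sum(.ztrunc_logpmf(yp, mu, family, th))
    if (!is.finite(v)) 1e10 else v
  }
  # analytic score for the truncated Poisson: dll/deta = y - mu/(1 - e^-mu)
  gr_count <- if (family == "poisson") {
    function(p) {
      mu <- exp(p[1] + p[2] * xp)
      r <- yp - mu / (1 - exp(-mu))
      -c(sum(r), sum(r * xp))
    }
  } else {
    NULL
  }
  m0 <- log(mean(yp))
  starts <- if (family == "negbin") {
    list(c(m0, 0, 0), c(0, 0, 1), c(m0, -0.1, 2))
  } else {
    list(c(m0, 0), c(0, 0), c(m0, -0.1))
  }
  oc <- .ml_optim(nll_count, starts, gr = gr_count)
  se_c <- sqrt(diag(solve(oc$hessian)))

  mk <- function(par, se, terms) {
    zval <- par / se
    tibble(
      term = terms, estimate = par, se = se, z_value = zval,
      p_value = 2 * pnorm(-abs(zval))
    )
  }
  ll <- -(oz$value + oc$value)
  k <- 2 + np
  structure(
    list(
      zero = mk(oz$par, se_z, c("(Intercept)", "covariate")),
      count = mk(oc$par[1:2], se_c[1:2], c("(Intercept)", "covariate")),
      theta = if (family == "negbin") exp(oc$par[3]) else NULL,
      family = family, loglik = ll, df = k, aic = 2 * k - 2 * ll,
      n = length(counts),
      converged = oz$convergence == 0 && oc$convergence == 0
    ),
    class = "hurdle_fit"
  )
}

#' @export
logLik.hurdle_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}
#' @export
AIC.hurdle_fit <- function(object, ...) object$aic

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf(
    "Hurdle model (%s counts), n = %d, logLik = %.2f, AIC = %.2f\n",
    x$family, x$n, x$loglik, x$aic
  ))
  cat("Zero part (logit presence):\n")
  print(x$zero)
  cat("Count part (log link, zero-truncated):\n")
  print(x$count)
  if (!is.null(x$theta)) cat(sprintf("theta (dispersion) = %.3f\n", x$theta))
  invisible(x)
}
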