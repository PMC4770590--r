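# First-principles linear fits: simple regression and Gaussian factor
# (dummy-coded) regression, with Gaussian log-likelihoods so fits can be
# ranked by AIC.

.gauss_loglik <- function(resid) {
  n <- length(resid)
  s2 <- sum(resid^2) / n # ML variance
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Simple linear regression by closed-form least squares
#'
#' @param x,y Numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return A list of class `linfit`: `intercept, slope`, standard errors,
#'   `r_squared`, `adj_r_squared` (`1 - (1-R^2)(n-1)/(n-2)`), two-sided
#'   t-test `p_value` for the slope, residual variance, log-likelihood and
#'   AIC.
#' @export
linfit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete observations")
  if (var(x) == 0) abort("x is degenerate (zero variance)")
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - yb)^2)
  s2 <- rss / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_intercept <- sqrt(s2 * (1 / n + xb^2 / sxx))
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  tval <- slope / se_slope
  ll <- .gauss_loglik(resid)
  structure(
    list(
      intercept = intercept, slope = slope,
      se_intercept = se_intercept, se_slope = se_slope,
      r_squared = r2,
      adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
      t_value = tval,
      p_value = 2 * pt(-abs(tval), df = n - 2),
      sigma2 = s2, n = n, df = 3,
      loglik = ll, aic = 2 * 3 - 2 * ll,
      fitted = intercept + slope * x, residuals = resid
    ),
    class = "linfit"
  )
}

#' Gaussian factor regression against a reference level
#'
#' Identity-link Gaussian fit with dummy coding: estimates are group-mean
#' differences from the reference level, with pooled-variance standard
#' errors, t statistics and p-values — the year-effect comparison used for
#' monthly prey-capture means.
#'
#' @param response Numeric response (e.g. per-trip mean captures).
#' @param labels Factor or vector of group labels (e.g. year).
#' @param reference Reference level.
#' @return A list of class `glm_factor`: `terms` tibble (reference row has
#'   estimate 0 by definition; other rows are differences from reference),
#'   residual variance, log-likelihood, AIC.
#' @export
glm_factor <- function(response, labels, reference) {
  labels <- as.character(labels)
  stopifnot(length(response) == length(labels))
  if (!reference %in% labels) abort("reference level absent from labels")
  tab <- table(labels)
  if (length(tab) < 2) abort("need at least 2 levels")
  if (any(tab < 2)) abort("each level needs at least 2 observations")
  levs <- c(reference, setdiff(sort(names(tab)), reference))
  f <- factor(labels, levels = levs)
  X <- cbind(1, sapply(levs[-1], function(l) as.numeric(f == l)))
  colnames(X) <- c("(Intercept)", levs[-1])
  XtX <- crossprod(X)
  beta <- unname(solve(XtX, crossprod(X, response)))
  resid <- response - X %*% beta
  n <- length(response)
  p <- ncol(X)
  s2 <- sum(resid^2) / (n - p)
  se <- unname(sqrt(diag(solve(XtX)) * s2))
  tval <- drop(beta) / se
  ll <- .gauss_loglik(resid)
  terms <- tibble(
    term = c(paste0(reference, " (reference)"), levs[-1]),
    estimate = c(0, drop(beta)[-1]),
    se = c(NA, se[-1]),
    t_value = c(NA, tval[-1]),
    p_value = c(NA, 2 * pt(-abs(tval[-1]), df = n - p))
  )
  structure(
    list(
      terms = terms, intercept = drop(beta)[1], reference = reference,
      sigma2 = s2, n = n, df = p + 1,
      loglik = ll, aic = 2 * (p + 1) - 2 * ll,
      group_means = tapply(response, f, mean)
    ),
    class = "glm_factor"
  )
}

#' Rank fitted models by AIC
#'
#' `AIC = 2k - 2 logLik` for every fit; models must be fitted to the same
#' response (checked via the stored observation count).
#'
#' @param fits Named list of fitted objects (`linfit`, `glm_factor`,
#'   `gam_fit`, `hurdle_fit`).
#' @return Tibble `model, df, loglik, aic, delta_aic` in ascending AIC
#'   order.
#' @export
aic_compare <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- purrr::map_dbl(fits, "n")
  if (length(unique(ns)) != 1) abort("fits are not on identical responses")
  out <- tibble(
    model = names(fits),
    df = unname(purrr::map_dbl(fits, "df")),
    loglik = unname(purrr::map_dbl(fits, "loglik")),
    aic = unname(purrr::map_dbl(fits, "aic"))
  ) %>%
    arrange(.data$aic) %>%
    mutate(delta_aic = .data$aic - min(.data$aic))
  out
}

#' @export
logLik.linfit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}
#' @export
AIC.linfit <- function(object, ...) object$aic
#' @export
logLik.glm_factor <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}
#' @export
AIC.glm_factor <- function(object, ...) object$aic

#' @export
print.linfit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: slope %.4g (SE %.3g, p = %.3g), adj R^2 = %.3f, AIC = %.2f\n",
    x$slope, x$se_slope, x$p_value, x$adj_r_squared, x$aic
  ))
  invisible(x)
}

#' @export
print.glm_factor <- function(x, ...) {
  cat("Gaussian factor fit (reference:", x$reference, ")\n")
  print(x$terms)
  invisible(x)
}
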