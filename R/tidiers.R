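# broom-style tidiers for the fitted-model classes.

#' @exportS3Method generics::tidy
tidy.linfit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    statistic = c(NA, x$t_value),
    p.value = c(NA, x$p_value)
  )
}

#' @exportS3Method generics::glance
glance.linfit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    sigma = sqrt(x$sigma2), p.value = x$p_value,
    logLik = x$loglik, AIC = x$aic, nobs = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.glm_factor <- function(x, ...) {
  dplyr::rename(x$terms,
    estimate = "estimate", std.error = "se",
    statistic = "t_value", p.value = "p_value"
  )
}

#' @exportS3Method generics::glance
glance.glm_factor <- function(x, ...) {
  tibble(sigma = sqrt(x$sigma2), logLik = x$loglik, AIC = x$aic, nobs = x$n)
}

#' @exportS3Method generics::tidy
tidy.gam_fit <- function(x, ...) {
  tibble(
    term = "s(x)", edf = x$edf, statistic = x$f_value, p.value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.gam_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, edf = x$edf, lambda = x$lambda,
    argmax = x$argmax, logLik = x$loglik, AIC = x$aic, nobs = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.hurdle_fit <- function(x, ...) {
  bind_rows(
    mutate(x$zero, component = "zero", .before = 1),
    mutate(x$count, component = "count", .before = 1)
  ) %>%
    dplyr::rename(
      estimate = "estimate", std.error = "se",
      statistic = "z_value", p.value = "p_value"
    )
}

#' @exportS3Method generics::glance
glance.hurdle_fit <- function(x, ...) {
  tibble(
    family = x$family, theta = x$theta %||% NA_real_,
    logLik = x$loglik, AIC = x$aic, nobs = x$n, converged = x$converged
  )
}
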