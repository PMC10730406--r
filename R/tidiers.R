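# broom-style tidy()/glance() methods for fitted objects.

#' @method tidy ftp_htest
#' @export
tidy.ftp_htest <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value,
    method = x$method
  )
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "conc"),
    estimate = c(x$intercept, x$slope),
    std.error = suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
  )
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    nobs = nrow(x$points),
    conc.min = x$range[1L],
    conc.max = x$range[2L]
  )
}

#' @method tidy anova_dunnett
#' @export
tidy.anova_dunnett <- function(x, ...) {
  dplyr::mutate(x$comparisons, control = x$control)
}

#' @method glance anova_dunnett
#' @export
glance.anova_dunnett <- function(x, ...) {
  tibble(
    f.statistic = x$f_statistic,
    df = x$df[1L],
    df.residual = x$df[2L],
    p.value = x$p_anova,
    mc.reps = x$mc_reps
  )
}
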