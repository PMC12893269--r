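#' Repeated-measures correlation
#'
#' Common-slope ANCOVA formulation: fits `y ~ subject + x` with subject as a
#' factor, so per-subject offsets are removed and a single within-subject
#' slope is estimated. The correlation is
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` where `SS_x` is the
#' sequential sum of squares for `x` fitted after subject, with error degrees
#' of freedom `df = n_obs - n_subjects - 1`. The 95% confidence interval uses
#' the Fisher z-transform with standard error `1/sqrt(df - 1)`.
#'
#' @param x,y Numeric vectors of paired measurements.
#' @param subject Subject identifiers (coerced to factor).
#' @param conf Confidence level (default 0.95).
#' @return List of class `rmcorr_fit`: `r`, `df`, `ci_low`, `ci_high`,
#'   `slope`, `n_obs`, `n_subjects`.
#' @export
rmcorr <- function(x, y, subject, conf = 0.95) {
  subject <- factor(subject)
  if (length(unique(subject)) < 2) stop("need >= 2 subjects")
  if (length(x) != length(y) || length(x) != length(subject))
    stop("x, y and subject lengths differ")
  within_var <- tapply(x, subject, function(v) stats::var(v) > 0)
  if (!any(within_var, na.rm = TRUE))
    stop("x is constant within every subject; rmcorr undefined")
  fit <- stats::lm(y ~ subject + x)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]
  slope <- unname(stats::coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  ci <- rmcorr_ci(r, df, conf)
  structure(list(r = r, df = df, ci_low = ci[1], ci_high = ci[2],
                 slope = slope, n_obs = length(x),
                 n_subjects = nlevels(subject)),
            class = "rmcorr_fit")
}

#' Fisher-z confidence interval for a repeated-measures correlation
#'
#' Useful on its own to reconstruct intervals from published (r, df) pairs.
#'
#' @param r Correlation coefficient.
#' @param df Error degrees of freedom (`n_obs - n_subjects - 1`).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
rmcorr_ci <- function(r, df, conf = 0.95) {
  if (abs(r) >= 1) return(c(r, r))
  if (df <= 1) stop("df must exceed 1 for a Fisher-z interval")
  z <- atanh(r)
  se <- 1 / sqrt(df - 1)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r = %.3f, df = %d, 95%% CI = %.3f-%.3f\n",
              x$r, x$df, x$ci_low, x$ci_high))
  cat(sprintf("  n = %d observations, N = %d subjects, common slope = %.4g\n",
              x$n_obs, x$n_subjects, x$slope))
  invisible(x)
}
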