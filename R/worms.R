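# Sensitivity of fitness-curve slopes to the number of worms seeded, and the
# derived "comparable number of worms" tolerance.

#' Linear fit of slope on worm number
#'
#' Least-squares line of per-well fitness-curve slope (OD/h, typically over
#' the 24-96 h window) on the number of worms seeded. The dimensionless
#' \code{factor} — the variability of the per-worm effect relative to the
#' effect itself — is what converts into a comparable-worm-number tolerance.
#'
#' The defining phrase "standard deviation of the effect divided by the mean
#' effect" admits two readings, so both are reported: \code{factor} is the
#' coefficient's standard error divided by its absolute estimate from the
#' single pooled fit, and \code{factor_ratio_mode} is sd/|mean| across the
#' per-well effect estimates \code{(slope - intercept) / n}.
#'
#' @param worm_counts,slopes equal-length numeric vectors; at least 3
#'   distinct worm counts are required.
#' @return a \code{worm_slope_fit}: intercept (OD/h), effect_per_worm
#'   (OD/h per worm), se_effect, residuals, factor, factor_ratio_mode,
#'   degenerate (TRUE when the effect is 0 and the factor undefined).
#' @export
fit_slope_vs_worms <- function(worm_counts, slopes) {
  if (length(worm_counts) != length(slopes))
    fa_stop("parameter_error", "worm_counts and slopes must have equal length")
  if (length(unique(worm_counts)) < 3L)
    fa_stop("parameter_error", "need >= 3 distinct worm counts")
  fit <- stats::lm(slopes ~ worm_counts)
  # exact synthetic fits trip summary.lm's perfect-fit warning; degeneracy
  # is handled explicitly below
  co <- suppressWarnings(summary(fit))$coefficients
  eff <- co["worm_counts", "Estimate"]
  se <- co["worm_counts", "Std. Error"]
  degenerate <- !is.finite(eff) || eff == 0 || stats::sd(slopes) == 0
  per_well <- (slopes - co["(Intercept)", "Estimate"]) / worm_counts
  structure(list(
    intercept = co["(Intercept)", "Estimate"],
    effect_per_worm = eff, se_effect = se,
    residuals = unname(stats::residuals(fit)),
    factor = if (degenerate) NA_real_ else se / abs(eff),
    factor_ratio_mode = if (degenerate || mean(per_well) == 0) NA_real_
                        else stats::sd(per_well) / abs(mean(per_well)),
    degenerate = degenerate), class = "worm_slope_fit")
}

#' @export
print.worm_slope_fit <- function(x, ...) {
  cat(sprintf("<worm_slope_fit> slope = %.4g %+.4g * n_worms (OD/h)\n",
              x$intercept, x$effect_per_worm))
  if (x$degenerate) cat("  degenerate fit: per-worm effect is zero, factor undefined\n")
  else cat(sprintf("  factor = %.3f (pooled-fit mode), %.3f (ratio mode)\n",
                   x$factor, x$factor_ratio_mode))
  invisible(x)
}

#' Comparable-worm-number tolerance
#'
#' Converts the variability factor of [fit_slope_vs_worms()] into the range
#' of seeded worm numbers whose slope effect stays within one standard
#' deviation: tolerance = factor * mean_n, i.e. any count in
#' mean_n +/- tolerance is comparable. With the assay's factor of 0.29 and a
#' mean of 20 worms this is 20 +/- 5.8.
#'
#' @param factor non-negative variability factor.
#' @param mean_n mean number of worms seeded (> 0).
#' @return a \code{worm_range}: tolerance, lower, upper, mean_n, factor.
#' @export
comparable_worm_range <- function(factor, mean_n) {
  if (!is.finite(factor) || factor < 0)
    fa_stop("parameter_error", "factor must be a non-negative number")
  if (!is.finite(mean_n) || mean_n <= 0)
    fa_stop("parameter_error", "mean_n must be > 0")
  tol <- factor * mean_n
  structure(list(tolerance = tol, lower = mean_n - tol, upper = mean_n + tol,
                 mean_n = mean_n, factor = factor), class = "worm_range")
}

#' @export
print.worm_range <- function(x, ...) {
  cat(sprintf("<worm_range> %g +/- %.3g worms (factor %.3g): %.3g to %.3g\n",
              x$mean_n, x$tolerance, x$factor, x$lower, x$upper))
  invisible(x)
}
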