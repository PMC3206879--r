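# Curve-comparison statistics: the 2x2 signature chi-square test, Welch
# t-tests on endpoint / slope summaries, and the start-OD interaction model.

fc_test <- function(statistic, p_value, df, method) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method), class = "fc_test")
}

#' @export
print.fc_test <- function(x, ...) {
  cat(sprintf("<fc_test> %s\n  statistic = %.6g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Signature matrix of two curve groups
#'
#' The replicates of both groups are pooled and the mean relative OD per
#' timepoint computed; each (replicate, timepoint) value then scores one count
#' for its group, in the below-mean or above-mean column. The first timepoint
#' is excluded: after normalization every curve is exactly 1 there, so it
#' carries no information. Values exactly equal to the pooled mean (possible
#' only in noise-free synthetic data) are excluded and counted in the
#' \code{n_ties} attribute rather than assigned a side arbitrarily.
#'
#' @param group_a,group_b non-empty lists of normalized curves on one shared
#'   timepoint grid.
#' @return a \code{signature_matrix}: 2x2 integer matrix, rows = groups,
#'   columns = (below_mean, above_mean), with attributes \code{n_ties} and
#'   \code{n_timepoints} (scored timepoints).
#' @export
signature_matrix <- function(group_a, group_b) {
  group_a <- assert_curve_list(group_a, "group_a")
  group_b <- assert_curve_list(group_b, "group_b")
  all_curves <- c(group_a, group_b)
  if (!all(vapply(all_curves, `[[`, TRUE, "normalized")))
    fa_stop("state_error", "signature_matrix requires normalized curves")
  grid <- shared_grid(all_curves)
  vals <- do.call(rbind, lapply(all_curves, `[[`, "od"))[, -1L, drop = FALSE]
  pooled <- colMeans(vals)
  below <- sweep(vals, 2L, pooled, `<`)
  above <- sweep(vals, 2L, pooled, `>`)
  ia <- seq_along(group_a)
  counts <- rbind(group_a = c(sum(below[ia, ]), sum(above[ia, ])),
                  group_b = c(sum(below[-ia, ]), sum(above[-ia, ])))
  colnames(counts) <- c("below_mean", "above_mean")
  structure(counts, n_ties = length(vals) - sum(counts),
            n_timepoints = length(grid) - 1L, class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> counts of (replicate, timepoint) scores\n")
  print(unclass(x)[, , drop = FALSE])
  cat(sprintf("  %d timepoint(s) scored, %d tie(s) excluded\n",
              attr(x, "n_timepoints"), attr(x, "n_ties")))
  invisible(x)
}

# Pearson statistic for a 2x2 table in closed form; vectorized over cells.
pearson_2x2_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson chi-square with 1 degree of freedom and no continuity
#' correction, as used on signature matrices. All four marginals must be
#' positive.
#'
#' @param m a 2x2 matrix of non-negative counts (e.g. a [signature_matrix()]).
#' @return an \code{fc_test} with statistic, p_value, df = 1.
#' @export
chi_square_2x2 <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || !all(dim(m) == 2L) || any(m < 0) || anyNA(m))
    fa_stop("parameter_error", "'m' must be a 2x2 matrix of non-negative counts")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    fa_stop("degenerate_error",
            "degenerate table: all row and column marginals must be > 0")
  stat <- pearson_2x2_stat(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  fc_test(statistic = stat,
          p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
          df = 1L, method = "Pearson chi-square (2x2, no continuity correction)")
}

#' Welch t-test on curve summary features
#'
#' Reduces each replicate curve to a scalar feature — the mean of the last
#' \code{k_last} relative ODs (\code{"endpoint"}, sensitive to severe
#' effects) or the OLS slope over a window (\code{"slope"}, sensitive to
#' mid-curve effects) — and compares the two groups with a two-sample Welch
#' t-test.
#'
#' @param group_a,group_b lists of curves (normalized, or raw to be
#'   normalized on the fly); >= 2 per group.
#' @param feature \code{"endpoint"} or \code{"slope"}.
#' @param k_last number of final timepoints averaged for the endpoint.
#' @param t_start,t_end,hours slope window, as in [fit_slope()].
#' @return an \code{fc_test}. Note the Welch degrees of freedom are
#'   fractional. With zero variance in both groups the test degenerates: the
#'   statistic is 0 (equal means, p = 1) or infinite (p reported at the
#'   1e-300 floor).
#' @export
fc_t_test <- function(group_a, group_b, feature = c("endpoint", "slope"),
                      k_last = 1, t_start = 24, t_end = 96, hours = NULL) {
  feature <- match.arg(feature)
  group_a <- ensure_normalized(assert_curve_list(group_a, "group_a"))
  group_b <- ensure_normalized(assert_curve_list(group_b, "group_b"))
  if (length(group_a) < 2L || length(group_b) < 2L)
    fa_stop("sample_size_error", "need >= 2 replicates per group, got %d and %d",
            length(group_a), length(group_b))
  feat <- function(curves) vapply(curves, function(cv) {
    if (feature == "endpoint") mean(utils::tail(cv$od, k_last))
    else fit_slope(cv, t_start = t_start, t_end = t_end, hours = hours)$value
  }, 1)
  a <- feat(group_a)
  b <- feat(group_b)
  method <- sprintf("Welch t-test on %s", feature)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(fc_test(0, 1, length(a) + length(b) - 2L, method))
    return(fc_test(sign(mean(a) - mean(b)) * Inf, 1e-300,
                   length(a) + length(b) - 2L, method))
  }
  tt <- stats::t.test(a, b)
  fc_test(unname(tt$statistic), max(tt$p.value, 1e-300),
          unname(tt$parameter), method)
}

#' Effect of the start OD on fitness-curve dynamics
#'
#' Fits the linear model \code{od ~ time + time:start_od} across all
#' observations of a curve set and reports the coefficient and p-value of the
#' time-by-start-OD interaction, i.e. how much the curve's slope depends on
#' the amount of food initially dispensed. Comparing the fit on raw versus
#' start-OD-normalized curves quantifies how much of that dependence the
#' normalization removes.
#'
#' @param curves >= 3 curves with distinct start ODs.
#' @param use_normalized fit on relative OD (raw curves are normalized on the
#'   fly) or, if \code{FALSE}, on the raw readings (then all curves must be
#'   raw).
#' @return a \code{start_od_effect}: interaction_effect (OD per hour per
#'   start-OD unit), interaction_p, n_curves.
#' @export
start_od_effect <- function(curves, use_normalized = TRUE) {
  curves <- assert_curve_list(curves)
  if (length(curves) < 3L)
    fa_stop("parameter_error", "need >= 3 curves to estimate a start-OD effect")
  if (use_normalized) {
    curves <- ensure_normalized(curves)
  } else if (any(vapply(curves, `[[`, TRUE, "normalized"))) {
    fa_stop("state_error", "use_normalized = FALSE requires raw curves")
  }
  df <- curves_to_df(curves)
  if (length(unique(df$start_od)) < 2L)
    fa_stop("collinearity_error",
            "all start ODs are equal; the interaction is not identifiable")
  fit <- stats::lm(od ~ time_h + time_h:start_od, data = df)
  co <- summary(fit)$coefficients
  structure(list(interaction_effect = co["time_h:start_od", "Estimate"],
                 interaction_p = co["time_h:start_od", "Pr(>|t|)"],
                 n_curves = length(curves),
                 normalized = use_normalized),
            class = "start_od_effect")
}

#' @export
print.start_od_effect <- function(x, ...) {
  cat(sprintf("<start_od_effect> on %s curves (n = %d)\n  time:start_od effect = %.4g OD/h per OD unit, p = %.4g\n",
              if (x$normalized) "normalized" else "raw", x$n_curves,
              x$interaction_effect, x$interaction_p))
  invisible(x)
}
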