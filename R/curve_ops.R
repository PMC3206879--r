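#' Normalize a fitness curve by its start OD
#'
#' Divides every reading by the first reading so that all curves start at a
#' relative OD of exactly 1. This removes well-to-well variation in the amount
#' of food dispensed (the dominant technical nuisance in the assay) while
#' preserving all within-curve ratios. The raw start OD is kept in the
#' \code{start_od} field because it remains a covariate in the QTL model.
#'
#' Normalizing an already-normalized curve is an error, not a no-op: silently
#' renormalizing would hide bookkeeping bugs upstream.
#'
#' @param curve a raw [fitness_curve()].
#' @return the normalized curve.
#' @export
normalize_start_od <- function(curve) {
  if (!is_fitness_curve(curve))
    fa_stop("parameter_error", "'curve' must be a fitness_curve")
  if (curve$normalized)
    fa_stop("state_error", "curve for well '%s' is already normalized", curve$well)
  if (curve$od[1L] <= 0)
    fa_stop("degenerate_error",
            "cannot normalize well '%s': start OD is %g (must be > 0)",
            curve$well, curve$od[1L])
  out <- curve
  out$od <- curve$od / curve$od[1L]
  out$od[1L] <- 1  # exact by construction; guard against any FP surprise
  out$normalized <- TRUE
  out$start_od <- curve$od[1L]
  out
}

#' Normalize a set of curves
#'
#' @param curves list of raw [fitness_curve()] objects.
#' @param skip_normalized leave already-normalized curves untouched instead of
#'   raising an error (convenience for mixed sets inside the pipeline).
#' @return list of normalized curves.
#' @export
normalize_curves <- function(curves, skip_normalized = FALSE) {
  curves <- assert_curve_list(curves)
  lapply(curves, function(cv) {
    if (cv$normalized && skip_normalized) cv else normalize_start_od(cv)
  })
}

#' Mean relative OD per timepoint
#'
#' Arithmetic mean over a set of normalized curves sharing one timepoint grid;
#' this is the pooled mean curve underlying the signature chi-square test.
#'
#' @param curves non-empty list of normalized curves on a common grid.
#' @return data.frame with columns \code{time_h} and \code{od}.
#' @export
mean_curve <- function(curves) {
  curves <- assert_curve_list(curves)
  if (!all(vapply(curves, `[[`, TRUE, "normalized")))
    fa_stop("state_error", "mean_curve requires normalized curves")
  grid <- shared_grid(curves)
  od <- colMeans(do.call(rbind, lapply(curves, `[[`, "od")))
  data.frame(time_h = grid, od = as.numeric(od))
}

#' Slope-window presets
#'
#' The assay uses two slope windows: \code{"fig6"}, the 24-96 h range where
#' slopes are most sensitive to worm number, and \code{"supp"}, the explicit
#' timepoints 24, 96, 120 and 144 h used for the dispenser-based slope QTL
#' scan. Both are exposed because neither is canonical for all analyses.
#'
#' @param preset \code{"fig6"} or \code{"supp"}.
#' @return a list with \code{t_start}, \code{t_end} and \code{hours} suitable
#'   for splicing into [fit_slope()].
#' @export
slope_window <- function(preset = c("fig6", "supp")) {
  switch(match.arg(preset),
         fig6 = list(t_start = 24, t_end = 96, hours = NULL),
         supp = list(t_start = NULL, t_end = NULL, hours = c(24, 96, 120, 144)))
}

#' Least-squares slope of a fitness curve
#'
#' Ordinary least-squares slope of relative OD on time, in OD per hour, over
#' either a time range or an explicit set of timepoints. Missing timepoints
#' within the window are tolerated as long as at least two remain.
#'
#' @param curve a normalized [fitness_curve()].
#' @param t_start,t_end window bounds in hours (inclusive); ignored when
#'   \code{hours} is given.
#' @param hours optional explicit timepoints (hours) to use instead of a range.
#' @return an \code{fc_slope} object: \code{value} (OD/h), \code{window}
#'   (hours actually spanned), \code{n_points}.
#' @export
fit_slope <- function(curve, t_start = 24, t_end = 96, hours = NULL) {
  if (!is_fitness_curve(curve))
    fa_stop("parameter_error", "'curve' must be a fitness_curve")
  if (!curve$normalized)
    fa_stop("state_error", "slopes are defined on normalized (relative OD) curves")
  keep <- if (is.null(hours)) {
    curve$time_h >= t_start & curve$time_h <= t_end
  } else {
    curve$time_h %in% hours
  }
  tt <- curve$time_h[keep]
  yy <- curve$od[keep]
  if (length(tt) < 2L)
    fa_stop("window_error",
            "slope window contains %d timepoint(s); >= 2 required (well '%s')",
            length(tt), curve$well)
  tc <- tt - mean(tt)
  value <- sum(tc * (yy - mean(yy))) / sum(tc^2)
  structure(list(value = value, window = range(tt), n_points = length(tt)),
            class = "fc_slope")
}

#' @export
print.fc_slope <- function(x, ...) {
  cat(sprintf("<fc_slope> %.6g OD/h over %g-%g h (%d points)\n",
              x$value, x$window[1L], x$window[2L], x$n_points))
  invisible(x)
}
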