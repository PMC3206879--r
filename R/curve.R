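#' Construct a fitness curve
#'
#' A fitness curve (FC) is one well's OD600 time series together with its
#' plate metadata. In a feeding assay the OD measures the remaining bacterial
#' food suspension, so the curve of a well containing healthy worms declines
#' over time while blank wells stay flat.
#'
#' @param well well identifier (e.g. \code{"A01"}).
#' @param strain strain or line name seeded in the well.
#' @param treatment treatment name (e.g. an RNAi clone, or \code{"ev"} for the
#'   empty-vector control).
#' @param replicate replicate index (integer).
#' @param role one of \code{"sample"}, \code{"bacteria_blank"} (bacteria, no
#'   worms) or \code{"media_blank"} (neither).
#' @param time_h measurement times in hours; strictly increasing, first must
#'   be 0.
#' @param od OD600 readings, one per timepoint. Raw readings must be positive
#'   except for media blanks.
#' @param normalized logical; \code{TRUE} if the curve has already been
#'   divided by its start OD (in which case \code{od[1]} must equal 1).
#' @param start_od the raw first reading; retained through normalization
#'   because the start OD is a model covariate downstream. Defaults to
#'   \code{od[1]} for raw curves.
#' @return an object of class \code{fitness_curve}.
#' @seealso [normalize_start_od()], [fit_slope()]
#' @export
fitness_curve <- function(well, strain, treatment, replicate, role = "sample",
                          time_h, od, normalized = FALSE, start_od = NULL) {
  role <- match.arg(role, c("sample", "bacteria_blank", "media_blank"))
  time_h <- as.numeric(time_h)
  od <- as.numeric(od)
  if (length(time_h) != length(od) || length(od) < 2L)
    fa_stop("parameter_error", "a fitness curve needs >= 2 (time, od) pairs of equal length")
  if (anyNA(time_h) || anyNA(od) || !all(is.finite(od)))
    fa_stop("format_error", "non-finite time or od values in curve for well '%s'", well)
  if (any(diff(time_h) <= 0))
    fa_stop("format_error", "timepoints must be strictly increasing (well '%s')", well)
  if (time_h[1L] != 0)
    fa_stop("format_error", "first timepoint must be 0 h (well '%s')", well)
  if (!normalized && role != "media_blank" && any(od <= 0))
    fa_stop("format_error", "raw OD values must be positive (well '%s')", well)
  if (normalized && od[1L] != 1)
    fa_stop("format_error", "a normalized curve must start at relative OD 1 (well '%s')", well)
  if (is.null(start_od)) start_od <- if (normalized) NA_real_ else od[1L]
  structure(
    list(well = as.character(well), strain = as.character(strain),
         treatment = as.character(treatment), replicate = as.integer(replicate),
         role = role, time_h = time_h, od = od,
         normalized = isTRUE(normalized), start_od = as.numeric(start_od)),
    class = "fitness_curve")
}

#' @export
print.fitness_curve <- function(x, ...) {
  cat(sprintf("<fitness_curve> well %s | strain %s | %s | rep %d | %s | %s\n",
              x$well, x$strain, x$treatment, x$replicate, x$role,
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  %d timepoints, %g-%g h; od[1] = %.4g; start OD = %.4g\n",
              length(x$time_h), min(x$time_h), max(x$time_h), x$od[1L], x$start_od))
  invisible(x)
}

is_fitness_curve <- function(x) inherits(x, "fitness_curve")

assert_curve_list <- function(curves, arg = "curves", min_len = 1L) {
  if (is_fitness_curve(curves)) curves <- list(curves)
  if (!is.list(curves) || length(curves) < min_len ||
      !all(vapply(curves, is_fitness_curve, TRUE)))
    fa_stop("parameter_error", "'%s' must be a list of >= %d fitness_curve objects",
            arg, min_len)
  curves
}

#' Flatten a list of fitness curves to a long data frame
#'
#' @param curves a list of [fitness_curve()] objects.
#' @return a data.frame with one row per (well, timepoint) observation and
#'   columns well, strain, treatment, replicate, role, time_h, od, start_od,
#'   normalized.
#' @export
curves_to_df <- function(curves) {
  curves <- assert_curve_list(curves)
  n <- vapply(curves, function(cv) length(cv$time_h), 1L)
  data.frame(
    well = rep(vapply(curves, `[[`, "", "well"), n),
    strain = rep(vapply(curves, `[[`, "", "strain"), n),
    treatment = rep(vapply(curves, `[[`, "", "treatment"), n),
    replicate = rep(vapply(curves, `[[`, 1L, "replicate"), n),
    role = rep(vapply(curves, `[[`, "", "role"), n),
    time_h = unlist(lapply(curves, `[[`, "time_h"), use.names = FALSE),
    od = unlist(lapply(curves, `[[`, "od"), use.names = FALSE),
    start_od = rep(vapply(curves, `[[`, 1, "start_od"), n),
    normalized = rep(vapply(curves, `[[`, TRUE, "normalized"), n),
    stringsAsFactors = FALSE)
}

# shared grid of a curve set, or alignment error
shared_grid <- function(curves) {
  grid <- curves[[1L]]$time_h
  ok <- vapply(curves, function(cv) length(cv$time_h) == length(grid) &&
                 all(cv$time_h == grid), TRUE)
  if (!all(ok))
    fa_stop("alignment_error", "curves do not share a common timepoint grid")
  grid
}

ensure_normalized <- function(curves) {
  lapply(assert_curve_list(curves), function(cv)
    if (cv$normalized) cv else normalize_start_od(cv))
}
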