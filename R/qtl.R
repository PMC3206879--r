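# Single-marker QTL scan on fitness curves with permutation-based
# genome-wide thresholds.
#
# Model (full vs reduced, per marker):
#   od ~ time + time:start_od + marker     vs     od ~ time + time:start_od
# pooling all (line, replicate, timepoint) observations inside the time
# window; the marker term is tested with a 1-df nested-model F-test.
#
# The scan uses the Frisch-Waugh identity: with Q0 an orthonormal basis of
# the covariate column space and e the reduced-model residual, the RSS drop
# for a marker indicator z is (e'z)^2 / (z'z - ||Q0'z||^2). Because z is
# constant within a line, every inner product collapses onto per-line sums
# (rowsum of [e, Q0, 1]), so a whole 121-marker scan is one small matrix
# product — which is what makes 1000-permutation thresholds cheap.

# Build the observation-level design for the fc model.
# curves: normalized curves of one treatment; lines: line ids to include.
build_fc_design <- function(curves, lines, window = c(24, Inf)) {
  df <- curves_to_df(curves)
  df <- df[df$time_h >= window[1L] & df$time_h <= window[2L], , drop = FALSE]
  df <- df[df$strain %in% lines, , drop = FALSE]
  lines_used <- lines[lines %in% unique(df$strain)]
  if (nrow(df) < 6L || length(lines_used) < 2L)
    fa_stop("parameter_error",
            "too few observations/lines inside the time window for a scan")
  line_idx <- match(df$strain, lines_used)
  X0 <- cbind(1, df$time_h, df$time_h * df$start_od)
  finish_design(df$od, X0, line_idx, lines_used,
                model = "fc", window = window)
}

# Line-level design for the slope-based scan: X0 is just an intercept.
build_slope_design <- function(curves, lines, hours = c(24, 96, 120, 144)) {
  df_meta <- vapply(curves, `[[`, "", "strain")
  keep <- df_meta %in% lines
  curves <- curves[keep]
  strain <- df_meta[keep]
  slopes <- vapply(curves, function(cv) fit_slope(cv, hours = hours)$value, 1)
  y <- tapply(slopes, strain, mean)
  lines_used <- lines[lines %in% names(y)]
  y <- as.numeric(y[lines_used])
  if (length(lines_used) < 4L)
    fa_stop("parameter_error", "need >= 4 lines for a slope scan")
  finish_design(y, matrix(1, length(y), 1L), seq_along(y), lines_used,
                model = "slope", window = range(hours))
}

finish_design <- function(y, X0, line_idx, lines_used, model, window) {
  qr0 <- qr(X0)
  e <- qr.resid(qr0, y)
  RSS0 <- sum(e^2)
  p0 <- qr0$rank
  n <- length(y)
  df2 <- n - p0 - 1L
  if (df2 < 1L) fa_stop("parameter_error", "not enough residual degrees of freedom")
  Q0 <- qr.Q(qr0)[, seq_len(p0), drop = FALSE]
  U <- rowsum(cbind(e, Q0, 1), group = line_idx, reorder = TRUE)
  list(y = y, X0 = X0, line_idx = line_idx, lines = lines_used,
       U = U, RSS0 = RSS0, p0 = p0, n = n, df2 = df2,
       model = model, window = window)
}

# Scan F-tests for an allele matrix A (lines x markers, values 0/1/NA in the
# order design$lines). Returns neglog10_p, p, degenerate per marker.
scan_pvalues <- function(design, A, p_floor = 1e-300) {
  A <- as.matrix(A)
  nl <- length(design$lines)
  stopifnot(nrow(A) == nl)
  m <- ncol(A)
  neglog <- numeric(m)
  degen <- logical(m)
  has_na <- colSums(is.na(A)) > 0L
  s <- colSums(A, na.rm = TRUE)
  nn <- colSums(!is.na(A))
  mono <- s == 0 | s == nn

  if (design$RSS0 < 1e-14 * max(1, sum(design$y^2))) {
    # no residual variation at all: nothing for any marker to explain
    return(list(neglog10_p = numeric(m), p = rep(1, m),
                degenerate = rep(TRUE, m)))
  }

  fast <- which(!has_na & !mono)
  if (length(fast)) {
    M <- crossprod(design$U, A[, fast, drop = FALSE])  # (1+p0+1) x m
    ez <- M[1L, ]
    qz <- M[1L + seq_len(design$p0), , drop = FALSE]
    zz <- M[design$p0 + 2L, ]                # z entries are 0/1: z'z = sum(z)
    denom <- zz - colSums(qz^2)
    num <- ez^2 / denom
    ok <- is.finite(num) & denom > 1e-9
    RSSf <- pmax(design$RSS0 - num, 0)  # guard FP sign flips at exact fits
    Fst <- num / (RSSf / design$df2)
    lp <- stats::pf(Fst, 1, design$df2, lower.tail = FALSE, log.p = TRUE) / log(10)
    nl10 <- -lp
    nl10[!ok] <- 0
    degen[fast[!ok]] <- TRUE
    neglog[fast] <- nl10
  }
  slow <- which(has_na & !mono)
  for (j in slow) {
    res <- marker_f_subset(design, A[, j])
    neglog[j] <- res$neglog10_p
    degen[j] <- res$degenerate
  }
  degen[mono] <- TRUE
  neglog[mono] <- 0
  # perfect separation gives p = 0 (infinite F); place it at the p floor,
  # above every finite score so the argmax stays meaningful
  inf <- !is.finite(neglog)
  if (any(inf)) {
    cap <- max(-log10(p_floor), max(neglog[!inf], 0) + 1)
    neglog[inf] <- cap
  }
  list(neglog10_p = neglog, p = 10^(-neglog), degenerate = degen)
}

# Fallback for markers with missing calls: refit on the complete subset.
marker_f_subset <- function(design, z) {
  keep_line <- !is.na(z)
  keep <- keep_line[design$line_idx]
  y <- design$y[keep]
  X0 <- design$X0[keep, , drop = FALSE]
  zz <- z[design$line_idx][keep]
  if (length(unique(zz)) < 2L || length(y) <= ncol(X0) + 1L)
    return(list(neglog10_p = 0, degenerate = TRUE))
  qr0 <- qr(X0)
  e <- qr.resid(qr0, y)
  RSS0 <- sum(e^2)
  qrf <- qr(cbind(X0, zz))
  RSSf <- sum(qr.resid(qrf, y)^2)
  df2 <- length(y) - qrf$rank
  if (df2 < 1L)
    return(list(neglog10_p = 0, degenerate = TRUE))
  Fst <- max(RSS0 - RSSf, 0) / (RSSf / df2)
  lp <- stats::pf(Fst, 1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(neglog10_p = -lp, degenerate = FALSE)
}

allele_matrix <- function(genotypes, lines) {
  A <- (genotypes[lines, , drop = FALSE] == "H") * 1
  A[is.na(genotypes[lines, , drop = FALSE])] <- NA
  A
}

#' Marker significance in the fitness-curve QTL model
#'
#' p-value of one marker from the nested-model F-test of
#' \code{od ~ time + time:start_od + marker} against the model without the
#' marker, pooling all (line, replicate, timepoint) observations inside the
#' time window (default: 24 h to the last reading, the approximately linear
#' part of the curve). Lines with a missing allele are dropped for that
#' marker; a marker monomorphic after drops is flagged degenerate with
#' p = 1 by convention.
#'
#' @param curves curves of one treatment (raw curves are normalized on the
#'   fly); strains must match \code{names(alleles)}.
#' @param alleles named character vector of \code{"B"}/\code{"H"}/\code{NA}
#'   calls, one per line.
#' @param window numeric length 2, time window in hours.
#' @return a list: p_value, neglog10_p, degenerate, n_lines, n_obs.
#' @export
marker_model_pvalue <- function(curves, alleles, window = c(24, Inf)) {
  curves <- ensure_normalized(curves)
  design <- build_fc_design(curves, names(alleles), window)
  z <- (alleles[design$lines] == "H") * 1
  res <- scan_pvalues(design, matrix(z, ncol = 1L))
  list(p_value = res$p[1L], neglog10_p = res$neglog10_p[1L],
       degenerate = res$degenerate[1L],
       n_lines = length(design$lines), n_obs = design$n)
}

#' Genome-wide single-marker scan on fitness curves
#'
#' Applies [marker_model_pvalue()]'s F-test at every marker of the map and
#' returns the \eqn{-\log_{10} p} profile ordered by (chromosome, position).
#'
#' @param bundle an \code{experiment_bundle} (curves + layout + genotypes +
#'   map).
#' @param treatment treatment name to scan.
#' @param window time window in hours (default 24 h to last timepoint).
#' @return a \code{qtl_profile} data.frame: marker_id, chromosome, position,
#'   neglog10_p, degenerate; attributes treatment, model, window, n_obs,
#'   n_lines.
#' @export
genome_scan <- function(bundle, treatment, window = c(24, Inf)) {
  design <- scan_design(bundle, treatment, method = "fc", window = window)
  A <- allele_matrix(bundle$genotypes, design$lines)
  res <- scan_pvalues(design, A)
  profile_from(bundle$map, res, treatment, design)
}

#' Slope-based genome scan
#'
#' The dispenser-protocol variant: per line, the OLS slopes of its replicate
#' curves over explicit timepoints (default 24, 96, 120, 144 h) are averaged,
#' and each marker is tested in the single-marker model
#' \code{mean_slope ~ marker}.
#'
#' @param bundle an \code{experiment_bundle}.
#' @param treatment treatment name.
#' @param hours timepoints (hours) used for the slope.
#' @return a \code{qtl_profile} (model label \code{"slope"}).
#' @export
slope_genome_scan <- function(bundle, treatment, hours = c(24, 96, 120, 144)) {
  design <- scan_design(bundle, treatment, method = "slope", hours = hours)
  A <- allele_matrix(bundle$genotypes, design$lines)
  res <- scan_pvalues(design, A)
  profile_from(bundle$map, res, treatment, design)
}

scan_design <- function(bundle, treatment, method = c("fc", "slope"),
                        window = c(24, Inf), hours = c(24, 96, 120, 144)) {
  method <- match.arg(method)
  if (!treatment %in% bundle$layout$treatment)
    fa_stop("lookup_error", "treatment '%s' not present in the layout", treatment)
  lines <- rownames(bundle$genotypes)
  keep <- vapply(bundle$curves, function(cv)
    cv$role == "sample" && cv$treatment == treatment && cv$strain %in% lines,
    TRUE)
  curves <- ensure_normalized(bundle$curves[keep])
  if (method == "fc") build_fc_design(curves, lines, window)
  else build_slope_design(curves, lines, hours)
}

profile_from <- function(map, res, treatment, design) {
  prof <- data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
                     position = map$position, neglog10_p = res$neglog10_p,
                     degenerate = res$degenerate, stringsAsFactors = FALSE)
  attr(prof, "treatment") <- treatment
  attr(prof, "model") <- design$model
  attr(prof, "window") <- design$window
  attr(prof, "n_obs") <- design$n
  attr(prof, "n_lines") <- length(design$lines)
  class(prof) <- c("qtl_profile", "data.frame")
  prof
}

#' @export
print.qtl_profile <- function(x, ...) {
  peak <- x[which.max(x$neglog10_p), ]
  cat(sprintf("<qtl_profile> %s model, treatment '%s', %d markers, %d lines\n",
              attr(x, "model"), attr(x, "treatment"), nrow(x), attr(x, "n_lines")))
  cat(sprintf("  peak: %s (chr %d, pos %.2f), -log10 p = %.3f\n",
              peak$marker_id, peak$chromosome, peak$position, peak$neglog10_p))
  invisible(x)
}

#' Threshold from a list of permutation maxima
#'
#' Implements the ordered-list rule: the threshold at level \code{alpha} is
#' the \code{ceiling(alpha * n)}-th highest of the n per-permutation scan
#' maxima (e.g. the 50th highest of 1000 at alpha = 0.05).
#'
#' @param maxima numeric vector of per-permutation scan maxima.
#' @param alpha genome-wide significance level in (0, 1).
#' @return the threshold, on the \eqn{-\log_{10} p} scale.
#' @export
threshold_from_maxima <- function(maxima, alpha = 0.05) {
  n <- length(maxima)
  if (alpha <= 0 || alpha >= 1)
    fa_stop("parameter_error", "alpha must be in (0, 1)")
  k <- ceiling(alpha * n)
  if (k < 1 || n * alpha < 1)
    fa_stop("parameter_error",
            "n_perm * alpha must be >= 1 (got n = %d, alpha = %g)", n, alpha)
  sort(maxima, decreasing = TRUE)[k]
}

#' Permutation-based genome-wide significance threshold
#'
#' Curve sets are randomized over the lines: each permutation reassigns every
#' line's complete set of curves to a line label drawn without replacement
#' (replicates travel together, since they share a well-level environment),
#' the genome scan is rerun, and its maximum \eqn{-\log_{10} p} recorded.
#' The threshold is the \code{ceiling(alpha * n_perm)}-th highest maximum.
#'
#' @param bundle an \code{experiment_bundle}.
#' @param treatment treatment name.
#' @param n_perm number of permutations (1000 for the plate-reader protocol,
#'   300 for the dispenser/slope protocol).
#' @param alpha genome-wide level (default 0.05).
#' @param seed integer seed (the permutation stream is self-contained).
#' @param method \code{"fc"} (full curve model) or \code{"slope"}.
#' @param window,hours passed to the corresponding scan.
#' @return a \code{permutation_threshold}: alpha, n_perm, threshold, seed,
#'   and the full vector of maxima.
#' @export
permutation_threshold <- function(bundle, treatment, n_perm = 1000,
                                  alpha = 0.05, seed = 1,
                                  method = c("fc", "slope"),
                                  window = c(24, Inf),
                                  hours = c(24, 96, 120, 144)) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1)
    fa_stop("parameter_error", "alpha must be in (0, 1)")
  if (n_perm * alpha < 1)
    fa_stop("parameter_error", "n_perm * alpha must be >= 1")
  design <- scan_design(bundle, treatment, method, window, hours)
  A <- allele_matrix(bundle$genotypes, design$lines)
  nl <- nrow(A)
  maxima <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(nl)
    max(scan_pvalues(design, A[perm, , drop = FALSE])$neglog10_p)
  }, 1))
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 threshold = threshold_from_maxima(maxima, alpha),
                 seed = seed, maxima = maxima, method = method,
                 treatment = treatment),
            class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat(sprintf("<permutation_threshold> treatment '%s' (%s model)\n  alpha = %g, n_perm = %d -> threshold = %.3f (-log10 p)\n",
              x$treatment, x$method, x$alpha, x$n_perm, x$threshold))
  invisible(x)
}
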