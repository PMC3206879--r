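# Classification of individual RILs against the two parental references by
# signature chi-square tests, and the association of the resulting labels
# with the causal-locus genotype.

# p-value of the signature test, with the convention that a degenerate table
# (all scores tied, e.g. literally identical noise-free curve sets) carries
# no evidence of a difference: p = 1.
signature_p <- function(a, b) {
  tryCatch(chi_square_2x2(signature_matrix(a, b))$p_value,
           degenerate_error = function(e) 1)
}

#' Classify one RIL's curves against the parental references
#'
#' The RIL's curve set is compared to the Bristol (N2, RNAi-sensitive) and
#' Hawaii (CB4856, germline-RNAi-insensitive) reference sets by two separate
#' signature chi-square tests. The label is \code{"N2-like"} when the line
#' differs significantly from Hawaii but not from Bristol, \code{"CB-like"}
#' in the converse case, and \code{"uncategorized"} when it differs from both
#' or from neither — the minimal rule that produces the uncategorizable class
#' observed for lines of intermediate phenotype.
#'
#' Curves are compared on the relative-OD scale; re-expressing them as
#' percent of the normalized start is a fixed x100 rescale that the signature
#' test is invariant to, so it changes nothing here (it is applied in
#' reports for readability only).
#'
#' @param ril_curves,bristol_curves,hawaii_curves non-empty curve lists on a
#'   shared grid (raw curves are normalized on the fly).
#' @param alpha per-test significance level (default 0.05).
#' @param line_id optional line identifier carried into the result.
#' @return a \code{classification_result}: line_id, p_vs_bristol,
#'   p_vs_hawaii, label, alpha.
#' @export
classify_ril <- function(ril_curves, bristol_curves, hawaii_curves,
                         alpha = 0.05, line_id = NA_character_) {
  ril <- ensure_normalized(assert_curve_list(ril_curves, "ril_curves"))
  bri <- ensure_normalized(assert_curve_list(bristol_curves, "bristol_curves"))
  haw <- ensure_normalized(assert_curve_list(hawaii_curves, "hawaii_curves"))
  p_b <- signature_p(ril, bri)
  p_h <- signature_p(ril, haw)
  label <- if (p_h < alpha && p_b >= alpha) "N2-like"
           else if (p_b < alpha && p_h >= alpha) "CB-like"
           else "uncategorized"
  structure(list(line_id = line_id, p_vs_bristol = p_b, p_vs_hawaii = p_h,
                 label = label, alpha = alpha),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: %s (p vs Bristol = %.3g, p vs Hawaii = %.3g, alpha = %g)\n",
              x$line_id, x$label, x$p_vs_bristol, x$p_vs_hawaii, x$alpha))
  invisible(x)
}

#' Classify every RIL of an experiment bundle
#'
#' Pools each line's curves over the chosen treatments (by default the
#' germline-class treatments when the bundle carries a ground-truth record,
#' otherwise all treatments) and classifies them against the parental
#' reference curves with [classify_ril()].
#'
#' @param bundle an \code{experiment_bundle} whose layout contains the
#'   reference strains.
#' @param treatments treatments to pool; see above for the default.
#' @param causal_marker marker whose allele is attached per line (default:
#'   the bundle's ground-truth causal marker, if present).
#' @param alpha per-test level.
#' @param reference_strains names of the Bristol-like and Hawaii-like
#'   reference strains in the layout.
#' @return a \code{ril_classification} data.frame: line_id, p_vs_bristol,
#'   p_vs_hawaii, label, causal_allele, match.
#' @export
classify_rils <- function(bundle, treatments = NULL, causal_marker = NULL,
                          alpha = 0.05,
                          reference_strains = c(Bristol = "Bristol",
                                                Hawaii = "Hawaii")) {
  if (is.null(treatments)) {
    cls <- bundle$truth$treatment_classes
    treatments <- if (!is.null(cls)) names(cls)[unlist(cls) == "germline"]
                  else unique(bundle$layout$treatment[bundle$layout$role == "sample"])
    if (!length(treatments))
      treatments <- unique(bundle$layout$treatment[bundle$layout$role == "sample"])
  }
  missing_trt <- setdiff(treatments, bundle$layout$treatment)
  if (length(missing_trt))
    fa_stop("lookup_error", "treatment(s) not in layout: %s",
            paste(missing_trt, collapse = ", "))
  causal_marker <- causal_marker %||% bundle$truth$causal_marker
  pick <- function(strain) {
    keep <- vapply(bundle$curves, function(cv)
      cv$role == "sample" && cv$strain == strain && cv$treatment %in% treatments,
      TRUE)
    bundle$curves[keep]
  }
  bri <- pick(reference_strains[["Bristol"]])
  haw <- pick(reference_strains[["Hawaii"]])
  if (!length(bri) || !length(haw))
    fa_stop("lookup_error", "reference strain curves not found in bundle")
  lines <- rownames(bundle$genotypes)
  rows <- lapply(lines, function(ln) {
    res <- classify_ril(pick(ln), bri, haw, alpha = alpha, line_id = ln)
    allele <- if (!is.null(causal_marker)) bundle$genotypes[ln, causal_marker]
              else NA_character_
    match <- if (res$label == "uncategorized" || is.na(allele)) NA
             else (res$label == "N2-like" && allele == "B") ||
                  (res$label == "CB-like" && allele == "H")
    data.frame(line_id = ln, p_vs_bristol = res$p_vs_bristol,
               p_vs_hawaii = res$p_vs_hawaii, label = res$label,
               causal_allele = allele %||% NA_character_, match = match,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ril_classification", "data.frame")
  out
}

#' Summarize label-genotype association
#'
#' Counts how many lines could be categorized as parental-like and, of
#' those, how many carry the causal-locus allele their label predicts
#' (convention: N2-like matches the Bristol allele, CB-like the Hawaii
#' allele). Percentages are reported to one decimal.
#'
#' @param results a \code{ril_classification} data.frame (or any data.frame
#'   with \code{label} and optionally \code{causal_allele} columns), or a
#'   character vector of labels.
#' @param causal_alleles optional named allele vector overriding the
#'   \code{causal_allele} column.
#' @param convention named map from label to matching allele.
#' @return an \code{association_summary}: n_total, n_categorized,
#'   pct_categorized, pct_uncategorized, n_matched,
#'   pct_matched_of_categorized (NA when nothing was categorized).
#' @export
association_summary <- function(results, causal_alleles = NULL,
                                convention = c("N2-like" = "B",
                                               "CB-like" = "H")) {
  if (is.character(results))
    results <- data.frame(label = results, stringsAsFactors = FALSE)
  labels <- results$label
  alleles <- if (!is.null(causal_alleles)) {
    if (!is.null(names(causal_alleles)) && !is.null(results$line_id))
      unname(causal_alleles[results$line_id]) else unname(causal_alleles)
  } else results$causal_allele
  n_total <- length(labels)
  cat_mask <- labels %in% names(convention)
  n_cat <- sum(cat_mask)
  n_matched <- if (is.null(alleles)) NA_integer_ else
    sum(cat_mask & !is.na(alleles) & convention[labels] == alleles, na.rm = TRUE)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  structure(list(
    n_total = n_total, n_categorized = n_cat,
    pct_categorized = pct(n_cat, n_total),
    pct_uncategorized = pct(n_total - n_cat, n_total),
    n_matched = n_matched,
    pct_matched_of_categorized =
      if (n_cat == 0 || is.na(n_matched)) NA_real_ else pct(n_matched, n_cat)),
    class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat(sprintf("<association_summary> %d lines: %d categorized (%.1f%%), %d uncategorized (%.1f%%)\n",
              x$n_total, x$n_categorized, x$pct_categorized,
              x$n_total - x$n_categorized, x$pct_uncategorized))
  if (!is.na(x$pct_matched_of_categorized))
    cat(sprintf("  %d of the categorized match the causal allele (%.1f%%)\n",
                x$n_matched, x$pct_matched_of_categorized))
  invisible(x)
}
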