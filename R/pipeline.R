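# End-to-end orchestration: simulate or load an experiment, normalize,
# run the curve statistics, QTL scans with permutation thresholds, and the
# parental classification, writing every table plus a reproducibility
# manifest to one output directory.

#' Pipeline configuration
#'
#' Exactly one of \code{simulation} (a [simulation_config()]) or
#' \code{input_dir} (a directory readable by [read_experiment()]) must be
#' supplied.
#'
#' @param simulation simulation config, or NULL.
#' @param input_dir input directory, or NULL.
#' @param out_dir output directory for all result tables.
#' @param treatments treatments to scan for QTL; default: every sample
#'   treatment except the control class when ground truth is available,
#'   otherwise every sample treatment.
#' @param reference_strains layout names of the Bristol/Hawaii references.
#' @param alpha genome-wide and classification significance level.
#' @param n_perm permutations per treatment for the threshold (1000 for the
#'   full-curve protocol; 300 is the slope-protocol setting).
#' @param scan_window time window (hours) of the curve-model scan.
#' @param slope_hours timepoints for slope summaries.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it, so a rerun with the same config reproduces all outputs.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL, out_dir,
                            treatments = NULL,
                            reference_strains = c(Bristol = "Bristol",
                                                  Hawaii = "Hawaii"),
                            alpha = 0.05, n_perm = 1000,
                            scan_window = c(24, Inf),
                            slope_hours = c(24, 96, 120, 144), seed = 1) {
  if (is.null(simulation) == is.null(input_dir))
    fa_stop("parameter_error",
            "supply exactly one of 'simulation' or 'input_dir'")
  structure(list(simulation = simulation, input_dir = input_dir,
                 out_dir = out_dir, treatments = treatments,
                 reference_strains = reference_strains, alpha = alpha,
                 n_perm = as.integer(n_perm), scan_window = scan_window,
                 slope_hours = slope_hours, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    fa_stop("pipeline_error", "stage '%s' failed: %s", stage,
            conditionMessage(e))
  })
}

#' Run the full fitness-assay analysis pipeline
#'
#' Stages: load/simulate -> normalize -> parental FC statistics per
#' treatment -> QTL scan + permutation threshold per treatment ->
#' RIL classification and association summary -> manifest. All tables are
#' written under \code{config$out_dir}; the returned report lists the file
#' paths and headline results.
#'
#' @param config a [pipeline_config()].
#' @return a \code{pipeline_run} report (paths, association summary, QTL
#'   peak table, manifest), invisibly printable.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    fa_stop("parameter_error", "'config' must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  bundle <- run_stage("load", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- as.integer(child_seed(config$seed, 10L))
      simulate_experiment(sim)
    } else read_experiment(config$input_dir)
  })

  sample_trts <- unique(bundle$layout$treatment[bundle$layout$role == "sample"])
  treatments <- config$treatments
  if (is.null(treatments)) {
    cls <- bundle$truth$treatment_classes
    treatments <- if (!is.null(cls))
      intersect(sample_trts, names(cls)[unlist(cls) != "none"]) else sample_trts
  }
  unknown <- setdiff(treatments, sample_trts)
  if (length(unknown))
    fa_stop("lookup_error", "treatment(s) not present in the experiment: %s",
            paste(unknown, collapse = ", "))

  norm <- run_stage("normalize", normalize_curves(bundle$curves,
                                                  skip_normalized = TRUE))
  paths$normalized_readings <- file.path(config$out_dir, "normalized_readings.csv")
  write_readings(norm, paths$normalized_readings)

  # parental differential response per treatment (the RNAi-sensitivity readout)
  fc_rows <- run_stage("fc_stats", {
    ref <- config$reference_strains
    pick <- function(strain, trt) {
      keep <- vapply(norm, function(cv)
        cv$role == "sample" && cv$strain == strain && cv$treatment == trt, TRUE)
      norm[keep]
    }
    do.call(rbind, lapply(sample_trts, function(trt) {
      bri <- pick(ref[["Bristol"]], trt)
      haw <- pick(ref[["Hawaii"]], trt)
      if (length(bri) < 2L || length(haw) < 2L) return(NULL)
      sig <- tryCatch(chi_square_2x2(signature_matrix(bri, haw)),
                      degenerate_error = function(e)
                        fc_test(0, 1, 1L, "Pearson chi-square (degenerate)"))
      tend <- fc_t_test(bri, haw, feature = "endpoint")
      tslp <- fc_t_test(bri, haw, feature = "slope",
                        t_start = config$slope_hours[1L],
                        t_end = max(config$slope_hours))
      data.frame(treatment = trt,
                 method = c("chisq_signature", "t_endpoint", "t_slope"),
                 statistic = c(sig$statistic, tend$statistic, tslp$statistic),
                 df = c(sig$df, tend$df, tslp$df),
                 p_value = c(sig$p_value, tend$p_value, tslp$p_value),
                 stringsAsFactors = FALSE)
    }))
  })
  paths$fc_tests <- file.path(config$out_dir, "fc_tests.tsv")
  utils::write.table(fc_rows, paths$fc_tests, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  qtl_peaks <- run_stage("qtl_scan", {
    do.call(rbind, lapply(seq_along(treatments), function(i) {
      trt <- treatments[i]
      prof <- genome_scan(bundle, trt, window = config$scan_window)
      thr <- permutation_threshold(bundle, trt, n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   seed = child_seed(config$seed, 100L + i),
                                   window = config$scan_window)
      out <- as.data.frame(prof)
      out$threshold <- thr$threshold
      out$exceeds_threshold <- as.integer(out$neglog10_p > thr$threshold)
      f <- file.path(config$out_dir,
                     sprintf("qtl_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", trt)))
      utils::write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
      paths$qtl[[trt]] <<- f
      peak <- out[which.max(out$neglog10_p), ]
      data.frame(treatment = trt, peak_marker = peak$marker_id,
                 chromosome = peak$chromosome, neglog10_p = peak$neglog10_p,
                 threshold = thr$threshold,
                 significant = peak$neglog10_p > thr$threshold,
                 stringsAsFactors = FALSE)
    }))
  })

  assoc <- NULL
  classification <- run_stage("classify", {
    cls <- tryCatch(classify_rils(bundle, alpha = config$alpha,
                                  reference_strains = config$reference_strains),
                    fitassay_error = function(e) NULL)
    if (!is.null(cls)) {
      paths$classification <- file.path(config$out_dir, "classification.tsv")
      utils::write.table(cls, paths$classification, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      assoc <- association_summary(cls)
      paths$association <- file.path(config$out_dir, "association_summary.json")
      jsonlite::write_json(unclass(assoc), paths$association,
                           auto_unbox = TRUE, digits = NA)
    }
    cls
  })

  manifest <- run_stage("manifest", {
    files <- unlist(paths, use.names = FALSE)
    man <- list(
      package = "fitassay",
      version = as.character(utils::packageVersion("fitassay")),
      r_version = R.version.string,
      seed = config$seed,
      alpha = config$alpha, n_perm = config$n_perm,
      treatments = treatments,
      input = if (is.null(config$input_dir)) "simulated" else config$input_dir,
      created = format(Sys.time(), tz = "UTC"),
      checksums = as.list(tools::md5sum(files)))
    pm <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(man, pm, auto_unbox = TRUE, digits = NA)
    paths$manifest <- pm
    man
  })

  structure(list(paths = paths, qtl_peaks = qtl_peaks,
                 association = assoc, classification = classification,
                 manifest = manifest, bundle = bundle),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> outputs in %s\n", dirname(x$paths$manifest)))
  cat("QTL peaks:\n")
  print(x$qtl_peaks, row.names = FALSE)
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}
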