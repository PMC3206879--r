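# Synthetic-data generator. The raw plate data behind the assay are not
# public, so every downstream statistic is exercised against simulated
# experiments that reproduce the study's structure: 56 RILs + 2 parents
# genotyped at 121 markers on 6 chromosomes, 12 treatments in triplicate,
# OD600 readings every 24 h from 0 to 192 h, worm-well start ODs ~ N(0.83,
# 0.069^2), bacteria-blank start ODs ~ N(0.79, 0.065^2), and a causal
# RNAi-sensitivity locus on chromosome 1 (a ppw-1 proxy).

#' Simulate a marker map
#'
#' Markers are partitioned over chromosomes as evenly as possible and given
#' strictly increasing positions (arbitrary map units) within each chromosome.
#'
#' @param n_markers total marker count (default 121).
#' @param n_chromosomes chromosome count (default 6).
#' @param seed integer seed.
#' @return a \code{marker_map} data.frame: marker_id, chromosome, position.
#' @export
simulate_marker_map <- function(n_markers = 121, n_chromosomes = 6, seed = 1) {
  if (n_chromosomes < 1 || n_markers < n_chromosomes)
    fa_stop("parameter_error", "need n_markers >= n_chromosomes >= 1")
  sizes <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, {
    pos <- unlist(lapply(sizes, function(s) cumsum(stats::runif(s, 0.5, 2))),
                  use.names = FALSE)
  })
  as_marker_map(data.frame(
    marker_id = sprintf("M%03d", seq_len(n_markers)),
    chromosome = rep(seq_len(n_chromosomes), sizes),
    position = pos, stringsAsFactors = FALSE))
}

#' Simulate recombinant inbred line genotypes
#'
#' A first-order Markov model along each chromosome: the first marker is
#' Bristol or Hawaii with probability 1/2, and each subsequent marker switches
#' parental origin with probability \code{switch_prob}. Chromosomes are
#' independent and every line is fully homozygous (RILs are inbred). The
#' single switch probability stands in for the mating design; only the
#' marker autocorrelation matters to the statistics under test.
#'
#' @param map a \code{marker_map}.
#' @param n_rils number of lines (default 56).
#' @param switch_prob per-interval parent-switch probability in [0, 0.5].
#' @param seed integer seed.
#' @return character matrix (lines x markers) of \code{"B"}/\code{"H"} calls.
#' @export
simulate_ril_genotypes <- function(map, n_rils = 56, switch_prob = 0.1, seed = 1) {
  if (switch_prob < 0 || switch_prob > 0.5)
    fa_stop("parameter_error", "switch_prob must be in [0, 0.5]")
  if (n_rils < 1) fa_stop("parameter_error", "n_rils must be >= 1")
  n_mark <- nrow(map)
  with_seed(seed, {
    geno <- matrix(0L, n_rils, n_mark)
    for (chr in unique(map$chromosome)) {
      idx <- which(map$chromosome == chr)
      state <- stats::rbinom(n_rils, 1L, 0.5)
      geno[, idx[1L]] <- state
      for (j in idx[-1L]) {
        state <- (state + stats::rbinom(n_rils, 1L, switch_prob)) %% 2L
        geno[, j] <- state
      }
    }
  })
  out <- matrix(c("B", "H")[geno + 1L], n_rils, n_mark,
                dimnames = list(sprintf("RIL%03d", seq_len(n_rils)), map$marker_id))
  out
}

#' Simulate one fitness curve
#'
#' Food consumption is modelled as a declining logistic in relative OD,
#' \deqn{r(t) = 1 - D / (1 + e^{-k (t - t_m)})}
#' with depth \eqn{D \in [0,1]} (fraction of food eventually consumed), rate
#' \eqn{k} (per hour) and midpoint \eqn{t_m} (hours). Raw readings are
#' \code{start_od * r(t) * (1 + e_t)} with multiplicative Gaussian noise
#' \eqn{e_t \sim N(0, noise\_sd^2)} per timepoint. \code{D = 0} gives a flat
#' blank curve; small \code{D} or \code{k} gives the shallow curve of sick,
#' slow-feeding worms. This minimal three-parameter family covers both the
#' healthy and the sick curve shapes the assay distinguishes.
#'
#' @param D consumption depth in [0, 1].
#' @param k logistic rate per hour (>= 0).
#' @param t_m logistic midpoint in hours.
#' @param start_od raw start OD (> 0).
#' @param timepoints hours of measurement (first must be 0).
#' @param noise_sd per-timepoint multiplicative noise sd (>= 0).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @param well,strain,treatment,replicate,role curve metadata.
#' @return a raw [fitness_curve()].
#' @export
simulate_curve <- function(D, k, t_m, start_od, timepoints = seq(0, 192, by = 24),
                           noise_sd = 0, seed = NULL, well = "sim",
                           strain = "sim", treatment = "none", replicate = 1L,
                           role = "sample") {
  if (D < 0 || D > 1) fa_stop("parameter_error", "D must be in [0, 1]")
  if (k < 0) fa_stop("parameter_error", "k must be >= 0")
  if (start_od <= 0) fa_stop("parameter_error", "start_od must be > 0")
  if (noise_sd < 0) fa_stop("parameter_error", "noise_sd must be >= 0")
  r <- 1 - D / (1 + exp(-k * (timepoints - t_m)))
  eps <- with_seed(seed, stats::rnorm(length(timepoints), 0, noise_sd))
  od <- pmax(start_od * r * (1 + eps), 1e-6)
  fitness_curve(well = well, strain = strain, treatment = treatment,
                replicate = replicate, role = role,
                time_h = timepoints, od = od)
}

#' Default treatment panel
#'
#' Twelve treatments mirroring the assay's RNAi panel: the empty-vector
#' control (\code{"ev"}, no effect), seven germline-class clones whose effect
#' depends on the causal-locus allele (only Bristol-allele lines are
#' sensitive), and four general-class clones that affect every genotype.
#'
#' @return data.frame with columns treatment, class.
#' @export
default_treatments <- function() {
  data.frame(
    treatment = c("ev", "mel-26", "pos-1", "par-1", "smo-1", "par-6",
                  "gld-1", "let-502", "lin-31", "bli-3", "elt-2", "cel-1"),
    class = c("none", rep("germline", 7L), rep("general", 4L)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic experiment generator with defaults
#' matching the study conditions (see package vignette). Curve parameters:
#' healthy feeding is D = 0.8, k = 0.06/h, t_m = 90 h; an affected (sick)
#' population consumes less and slower, D = 0.3, k = 0.04/h, t_m = 110 h.
#' Seeded worm number varies around \code{worms_mean} and multiplies the
#' consumption rate k proportionally (k ~ n / worms_mean), which makes the
#' 24-96 h slope approximately linear in worm number.
#'
#' @param n_rils,n_markers,n_chromosomes population and map dimensions.
#' @param causal_marker marker id of the planted sensitivity locus; default:
#'   the middle marker of chromosome 1.
#' @param treatments data.frame(treatment, class) with class one of
#'   \code{"none"}, \code{"germline"}, \code{"general"}.
#' @param timepoints_h measurement grid in hours.
#' @param replicates replicate wells per (line, treatment).
#' @param worms_mean,worms_sd seeded worm-count distribution.
#' @param start_od_worms,start_od_blank c(mean, sd) of start ODs for worm
#'   wells and bacteria blanks.
#' @param noise_sd per-timepoint multiplicative noise sd.
#' @param curve_healthy,curve_affected list(D, k, t_m) per condition class.
#' @param switch_prob genotype Markov switch probability.
#' @param seed master seed; all child generators derive from it.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_rils = 56, n_markers = 121, n_chromosomes = 6,
                              causal_marker = NULL,
                              treatments = default_treatments(),
                              timepoints_h = seq(0, 192, by = 24),
                              replicates = 3, worms_mean = 20, worms_sd = 2,
                              start_od_worms = c(mean = 0.83, sd = 0.069),
                              start_od_blank = c(mean = 0.79, sd = 0.065),
                              noise_sd = 0.02,
                              curve_healthy = list(D = 0.8, k = 0.06, t_m = 90),
                              curve_affected = list(D = 0.3, k = 0.04, t_m = 110),
                              switch_prob = 0.1, seed = 1) {
  if (any(c(start_od_worms[2L], start_od_blank[2L], noise_sd, worms_sd) < 0))
    fa_stop("parameter_error", "all spread parameters must be >= 0")
  if (length(timepoints_h) < 2L || timepoints_h[1L] != 0 || any(diff(timepoints_h) <= 0))
    fa_stop("parameter_error", "timepoints_h must start at 0 and strictly increase")
  if (replicates < 1) fa_stop("parameter_error", "replicates must be >= 1")
  if (!all(c("treatment", "class") %in% names(treatments)) ||
      !all(treatments$class %in% c("none", "germline", "general")))
    fa_stop("parameter_error",
            "treatments must be a data.frame(treatment, class) with classes none/germline/general")
  for (p in list(curve_healthy, curve_affected))
    if (p$D < 0 || p$D > 1 || p$k < 0)
      fa_stop("parameter_error", "curve parameters require D in [0,1] and k >= 0")
  structure(list(
    n_rils = n_rils, n_markers = n_markers, n_chromosomes = n_chromosomes,
    causal_marker = causal_marker, treatments = treatments,
    timepoints_h = timepoints_h, replicates = as.integer(replicates),
    worms_mean = worms_mean, worms_sd = worms_sd,
    start_od_worms = start_od_worms, start_od_blank = start_od_blank,
    noise_sd = noise_sd, curve_healthy = curve_healthy,
    curve_affected = curve_affected, switch_prob = switch_prob,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate a complete plate experiment
#'
#' Generates the marker map, RIL genotypes and one fitness curve per
#' (line, treatment, replicate) well, always including the Bristol and Hawaii
#' parental reference strains and a bacteria-blank row per treatment, plus a
#' ground-truth record sufficient to score recovery downstream.
#'
#' Germline-class treatments assign the affected curve parameters only to
#' lines carrying the Bristol allele at the causal marker (the
#' RNAi-sensitive background); general-class treatments affect every line;
#' the empty-vector class affects none. The per-well worm count scales the
#' consumption rate k by n / worms_mean.
#'
#' @param config a [simulation_config()].
#' @return an \code{experiment_bundle}: curves, layout, genotypes, map, truth.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    fa_stop("parameter_error", "'config' must come from simulation_config()")
  map <- simulate_marker_map(config$n_markers, config$n_chromosomes,
                             seed = child_seed(config$seed, 1L))
  genotypes <- simulate_ril_genotypes(map, config$n_rils, config$switch_prob,
                                      seed = child_seed(config$seed, 2L))
  causal <- config$causal_marker
  if (is.null(causal)) {
    chr1 <- map$marker_id[map$chromosome == 1]
    causal <- chr1[ceiling(length(chr1) / 2)]
  }
  if (!causal %in% map$marker_id)
    fa_stop("config_error", "causal marker '%s' absent from map", causal)

  lines <- c(rownames(genotypes), "Bristol", "Hawaii")
  causal_allele <- c(genotypes[, causal],
                     Bristol = "B", Hawaii = "H")[lines]
  curves <- vector("list",
                   length(lines) * nrow(config$treatments) * config$replicates +
                     nrow(config$treatments) * config$replicates)
  worm_counts <- integer(0)
  i <- 0L
  with_seed(child_seed(config$seed, 3L), {
    for (ti in seq_len(nrow(config$treatments))) {
      trt <- config$treatments$treatment[ti]
      cls <- config$treatments$class[ti]
      for (ln in lines) {
        affected <- (cls == "general") ||
          (cls == "germline" && identical(causal_allele[[ln]], "B"))
        pars <- if (affected) config$curve_affected else config$curve_healthy
        for (r in seq_len(config$replicates)) {
          i <- i + 1L
          start <- max(stats::rnorm(1, config$start_od_worms[1L],
                                    config$start_od_worms[2L]), 0.05)
          n_worms <- max(1L, as.integer(round(
            stats::rnorm(1, config$worms_mean, config$worms_sd))))
          w <- sprintf("W%04d", i)
          curves[[i]] <- simulate_curve(
            D = pars$D, k = pars$k * n_worms / config$worms_mean,
            t_m = pars$t_m, start_od = start,
            timepoints = config$timepoints_h, noise_sd = config$noise_sd,
            well = w, strain = ln, treatment = trt, replicate = r,
            role = "sample")
          worm_counts[w] <- n_worms
        }
      }
      # a blank row per treatment: same bacteria, no worms, flat curve
      for (r in seq_len(config$replicates)) {
        i <- i + 1L
        start <- max(stats::rnorm(1, config$start_od_blank[1L],
                                  config$start_od_blank[2L]), 0.05)
        w <- sprintf("W%04d", i)
        curves[[i]] <- simulate_curve(
          D = 0, k = 0, t_m = 0, start_od = start,
          timepoints = config$timepoints_h, noise_sd = config$noise_sd,
          well = w, strain = "bacteria", treatment = trt, replicate = r,
          role = "bacteria_blank")
      }
    }
  })
  curves <- curves[seq_len(i)]
  names(curves) <- vapply(curves, `[[`, "", "well")
  layout <- do.call(rbind, lapply(curves, function(cv)
    data.frame(well = cv$well, strain = cv$strain, treatment = cv$treatment,
               replicate = cv$replicate, role = cv$role,
               stringsAsFactors = FALSE)))
  rownames(layout) <- NULL
  effects <- config$treatments
  effects$D_healthy <- config$curve_healthy$D
  effects$D_affected <- ifelse(effects$class == "none",
                               config$curve_healthy$D, config$curve_affected$D)
  truth <- list(causal_marker = causal,
                treatment_classes = as.list(stats::setNames(
                  config$treatments$class, config$treatments$treatment)),
                effects = effects,
                curve_healthy = config$curve_healthy,
                curve_affected = config$curve_affected,
                worm_counts = as.list(worm_counts),
                seed = config$seed)
  new_bundle(curves, layout, genotypes, map, truth)
}
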