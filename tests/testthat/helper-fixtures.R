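# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# a raw curve on the standard 24 h grid with given OD values
raw_curve <- function(od, time_h = seq(0, by = 24, length.out = length(od)),
                      well = "A01", strain = "s", treatment = "t",
                      replicate = 1L, role = "sample") {
  fitness_curve(well = well, strain = strain, treatment = treatment,
                replicate = replicate, role = role, time_h = time_h, od = od)
}

# a normalized curve built directly (od[1] must be 1)
norm_curve <- function(od, time_h = seq(0, by = 24, length.out = length(od)),
                       well = "A01", strain = "s", treatment = "t",
                       replicate = 1L, start_od = 0.8) {
  fitness_curve(well = well, strain = strain, treatment = treatment,
                replicate = replicate, role = "sample", time_h = time_h,
                od = od, normalized = TRUE, start_od = start_od)
}

# normalized curve with exact linear decline plus additive noise after t=0;
# satisfies the scan's linear model exactly (used for null calibration)
linear_curve <- function(slope, time_h = seq(0, 192, by = 24), noise_sd = 0,
                         strain = "s", well = "A01", replicate = 1L,
                         start_od = 0.8, intercept = 1) {
  od <- intercept + slope * time_h
  if (noise_sd > 0) od[-1L] <- od[-1L] + stats::rnorm(length(od) - 1L, 0, noise_sd)
  od[1L] <- 1
  norm_curve(od, time_h = time_h, well = well, strain = strain,
             replicate = replicate, start_od = start_od)
}

# small fast simulation config for end-to-end tests
tiny_config <- function(seed = 1, n_rils = 12, treatments =
                          data.frame(treatment = c("ev", "rnaiA"),
                                     class = c("none", "germline")),
                        ...) {
  simulation_config(n_rils = n_rils, n_markers = 24, n_chromosomes = 6,
                    treatments = treatments, seed = seed, ...)
}

# bundle with line-level mean-slope structure planted directly through
# linear curves: slope = base + effect * (allele at causal marker == "H")
slope_bundle <- function(n_lines = 38, base = -0.010, effect = 0.005,
                         rep_sd = 0.001, replicates = 3, seed = 1,
                         n_markers = 24, n_chromosomes = 6) {
  set.seed(seed)
  map <- simulate_marker_map(n_markers, n_chromosomes, seed = seed + 1)
  geno <- simulate_ril_genotypes(map, n_lines, 0.1, seed = seed + 2)
  chr1 <- map$marker_id[map$chromosome == 1]
  causal <- chr1[ceiling(length(chr1) / 2)]
  curves <- list(); i <- 0
  for (ln in rownames(geno)) {
    sl <- base + effect * (geno[ln, causal] == "H")
    for (r in seq_len(replicates)) {
      i <- i + 1
      curves[[i]] <- linear_curve(sl + rnorm(1, 0, rep_sd),
                                  strain = ln, well = sprintf("W%04d", i),
                                  replicate = r)
    }
  }
  names(curves) <- vapply(curves, `[[`, "", "well")
  layout <- curves_to_df(curves)
  layout <- unique(layout[c("well", "strain", "treatment", "replicate", "role")])
  bundle <- fitassay:::new_bundle(curves, layout, geno, map,
                                  truth = list(causal_marker = causal, seed = seed))
  bundle
}
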