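test_that("marker F-test agrees with an explicit lm nested-model oracle", {
  set.seed(61)
  tp <- c(0, 24, 48, 72)
  for (rep in 1:5) {
    lines <- paste0("L", 1:6)
    alleles <- setNames(c("B", "B", "B", "H", "H", "H"), lines)
    curves <- unlist(lapply(lines, function(ln) {
      lapply(1:2, function(r)
        norm_curve(c(1, runif(3, 0.3, 0.99)), time_h = tp,
                   well = paste0(ln, r), strain = ln, replicate = r,
                   start_od = runif(1, 0.7, 0.9))) }), recursive = FALSE)
    res <- marker_model_pvalue(curves, alleles)

    df <- curves_to_df(curves)
    df <- df[df$time_h >= 24, ]
    df$allele <- alleles[df$strain]
    full <- lm(od ~ time_h + time_h:start_od + allele, data = df)
    red <- lm(od ~ time_h + time_h:start_od, data = df)
    p_lm <- anova(red, full)[2, "Pr(>F)"]
    expect_equal(-log10(res$p_value), -log10(p_lm), tolerance = 1e-8)
  }
})

test_that("degenerate and extreme markers are handled by convention", {
  tp <- seq(0, 96, 24)
  lines <- paste0("L", 1:6)
  # the two allele groups differ by an exact level shift inside the window,
  # so the marker main effect absorbs it completely (perfect separation)
  curves <- lapply(seq_along(lines), function(i)
    norm_curve(c(1, 0.9, 0.8, 0.7, 0.6) - c(0, rep(0.4 * (i > 3), 4)),
               time_h = tp, well = paste0("W", i), strain = lines[i],
               start_od = 0.7 + 0.02 * i))
  # monomorphic marker: flagged, p = 1
  mono <- marker_model_pvalue(curves, setNames(rep("B", 6), lines))
  expect_true(mono$degenerate)
  expect_equal(mono$p_value, 1)

  # noise-free perfect separation: p at the floor, still finite on -log10
  sep <- marker_model_pvalue(curves, setNames(c("B", "B", "B", "H", "H", "H"), lines))
  expect_false(sep$degenerate)
  expect_true(is.finite(sep$neglog10_p))
  expect_gt(sep$neglog10_p, 50)

  # global allele relabelling leaves the p-value unchanged
  flip <- setNames(c("H", "H", "H", "B", "B", "B"), lines)
  expect_equal(marker_model_pvalue(curves, flip)$neglog10_p, sep$neglog10_p)

  # missing-allele lines are dropped for that marker only
  with_na <- setNames(c("B", "B", NA, "H", "H", "H"), lines)
  res_na <- marker_model_pvalue(curves, with_na)
  expect_false(res_na$degenerate)
  expect_true(res_na$p_value > 0 && res_na$p_value <= 1)
})

test_that("null marker p-values are approximately uniform", {
  # curves generated under the scan's own linear model (linear decline,
  # additive iid noise), marker assigned independently of phenotype
  set.seed(67)
  pvals <- replicate(400, {
    lines <- paste0("L", 1:20)
    curves <- lapply(lines, function(ln)
      linear_curve(-0.003, time_h = seq(0, 96, 24), noise_sd = 0.02,
                   strain = ln, well = ln, start_od = runif(1, 0.7, 0.9)))
    alleles <- setNames(sample(rep(c("B", "H"), 10)), lines)
    marker_model_pvalue(curves, alleles)$p_value
  })
  expect_lt(suppressWarnings(ks.test(pvals, "punif"))$statistic, 0.1)
})

test_that("genome scans cover the map and respect treatment lookup", {
  b <- simulate_experiment(tiny_config(seed = 71))
  prof <- genome_scan(b, "rnaiA")
  expect_s3_class(prof, "qtl_profile")
  expect_equal(nrow(prof), nrow(b$map))
  expect_identical(prof$marker_id, b$map$marker_id)
  expect_true(all(is.finite(prof$neglog10_p)))
  expect_error(genome_scan(b, "absent"), class = "lookup_error")
})

test_that("permutation thresholds follow the ordered-maxima rule", {
  set.seed(73)
  maxima <- sample(as.numeric(1:1000))
  # 50th highest of 1000 at alpha = 0.05
  expect_equal(threshold_from_maxima(maxima, 0.05), 951)
  # boundary: alpha * n = n picks the smallest maximum
  expect_equal(threshold_from_maxima(maxima, 0.9995), 1)
  expect_equal(threshold_from_maxima(as.numeric(1:300), 0.05), 286)
  expect_error(threshold_from_maxima(1:10, 0.05), class = "parameter_error")
  # monotone in alpha on one list
  expect_gte(threshold_from_maxima(maxima, 0.01),
             threshold_from_maxima(maxima, 0.05))
})

test_that("permutation thresholds are deterministic and seed-dependent", {
  b <- simulate_experiment(tiny_config(seed = 79))
  t1 <- permutation_threshold(b, "ev", n_perm = 60, seed = 5)
  t2 <- permutation_threshold(b, "ev", n_perm = 60, seed = 5)
  expect_identical(t1$maxima, t2$maxima)
  expect_identical(t1$threshold, t2$threshold)
  expect_error(permutation_threshold(b, "ev", n_perm = 10, alpha = 0.05),
               class = "parameter_error")
})

test_that("slope scan detects a planted line-level slope difference", {
  # 38 lines, mean-slope difference 0.005 OD/h between allele classes,
  # replicate slope sd 0.001
  b <- slope_bundle(n_lines = 38, base = -0.010, effect = 0.005,
                    rep_sd = 0.001, seed = 83)
  prof <- slope_genome_scan(b, "t", hours = c(24, 96, 120, 144))
  thr <- permutation_threshold(b, "t", n_perm = 300, seed = 7,
                               method = "slope")
  causal <- b$truth$causal_marker
  expect_gt(prof$neglog10_p[prof$marker_id == causal], thr$threshold)
  expect_equal(prof$marker_id[which.max(prof$neglog10_p)], causal)
})

test_that("a slope scan with no slope variation is flat at p = 1", {
  b <- slope_bundle(n_lines = 12, base = -0.008, effect = 0, rep_sd = 0,
                    seed = 89)
  prof <- slope_genome_scan(b, "t")
  expect_true(all(prof$neglog10_p == 0))
  expect_true(all(prof$degenerate))
})

test_that("aggregated scan equals per-marker refits under permutation", {
  # the rowsum-collapsed scan must match marker_model_pvalue marker by marker
  b <- simulate_experiment(tiny_config(seed = 97, n_rils = 8))
  prof <- genome_scan(b, "rnaiA")
  lines <- rownames(b$genotypes)
  keep <- vapply(b$curves, function(cv)
    cv$role == "sample" && cv$treatment == "rnaiA" && cv$strain %in% lines, TRUE)
  curves <- b$curves[keep]
  for (m in sample(b$map$marker_id, 5)) {
    ref <- marker_model_pvalue(curves, setNames(b$genotypes[, m], lines))
    expect_equal(prof$neglog10_p[prof$marker_id == m], ref$neglog10_p,
                 tolerance = 1e-8)
  }
})
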