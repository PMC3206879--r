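test_that("start-OD normalization divides by the first reading", {
  cv <- raw_curve(c(0.8, 0.6, 0.4))
  n <- normalize_start_od(cv)
  expect_equal(n$od, c(1, 0.75, 0.5))
  expect_identical(n$od[1], 1)
  expect_equal(n$start_od, 0.8)

  flat <- normalize_start_od(raw_curve(c(0.5, 0.5, 0.5)))
  expect_equal(flat$od, c(1, 1, 1))

  expect_error(normalize_start_od(n), class = "state_error")
  zero <- raw_curve(c(0, 0.1, 0.2), role = "media_blank")
  expect_error(normalize_start_od(zero), class = "degenerate_error")
})

test_that("normalization preserves within-curve ratios", {
  set.seed(21)
  for (rep in 1:20) {
    od <- runif(9, 0.2, 1.2)
    cv <- raw_curve(od)
    n <- normalize_start_od(cv)
    i <- sample(9, 1); j <- sample(9, 1)
    expect_equal(n$od[i] / n$od[j], od[i] / od[j])
  }
})

test_that("mean_curve averages normalized curves on a shared grid", {
  a <- norm_curve(c(1, 0.8))
  b <- norm_curve(c(1, 0.6))
  mc <- mean_curve(list(a, b))
  expect_equal(mc$od, c(1, 0.7))
  expect_equal(mean_curve(list(a))$od, a$od)
  # mean of normalized curves always starts at exactly 1
  set.seed(3)
  ms <- mean_curve(lapply(1:5, function(i)
    norm_curve(c(1, runif(8)), well = paste0("W", i))))
  expect_identical(ms$od[1], 1)

  c2 <- norm_curve(c(1, 0.5), time_h = c(0, 48))
  expect_error(mean_curve(list(a, c2)), class = "alignment_error")
  expect_error(mean_curve(list(raw_curve(c(0.8, 0.6)))), class = "state_error")
  expect_error(mean_curve(list()), class = "parameter_error")
})

test_that("fit_slope computes the OLS slope over the requested window", {
  cv <- norm_curve(c(1, 1.0, 0.9, 0.8, 0.7), time_h = c(0, 24, 48, 72, 96))
  sl <- fit_slope(cv, 24, 96)
  expect_equal(sl$value, -1 / 240)
  expect_equal(sl$n_points, 4)

  flat <- fit_slope(norm_curve(rep(1, 9)), 24, 192)
  expect_equal(flat$value, 0)

  # oracle: closed-form normal equations on the supplementary-window points
  cv2 <- norm_curve(c(1, 1.00, 0.85, 0.70, 0.55),
                    time_h = c(0, 24, 96, 120, 144))
  sl2 <- fit_slope(cv2, hours = c(24, 96, 120, 144))
  x <- c(24, 96, 120, 144); y <- c(1, 0.85, 0.70, 0.55)
  expect_equal(sl2$value, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  expect_equal(sl2$value, -28.8 / 8064)

  expect_error(fit_slope(cv, 90, 95), class = "window_error")
  expect_error(fit_slope(raw_curve(c(0.8, 0.7, 0.6))), class = "state_error")
})

test_that("fit_slope is shift-invariant and scales linearly", {
  set.seed(31)
  od <- c(1, sort(runif(8, 0.2, 0.99), decreasing = TRUE))
  base <- fit_slope(norm_curve(od), 24, 192)$value
  shifted <- norm_curve(od + 0, start_od = 1)
  shifted$od <- od + 0.3  # direct field edit keeps metadata, adds a constant
  expect_equal(fit_slope(shifted, 24, 192)$value, base)
  scaled <- shifted; scaled$od <- od * 3
  expect_equal(fit_slope(scaled, 24, 192)$value, 3 * base)
})

test_that("slope_window presets expose the two published windows", {
  expect_equal(slope_window("fig6")[c("t_start", "t_end")],
               list(t_start = 24, t_end = 96))
  expect_equal(slope_window("supp")$hours, c(24, 96, 120, 144))
})

test_that("experiment tables round-trip through CSV", {
  b <- simulate_experiment(tiny_config(seed = 13))
  dir <- withr::local_tempdir()
  write_experiment(b, dir)
  b2 <- read_experiment(dir)
  expect_equal(curves_to_df(b2$curves), curves_to_df(b$curves),
               tolerance = 1e-12)
  expect_identical(b2$genotypes, b$genotypes)
  expect_equal(b2$map$position, b$map$position, tolerance = 1e-12)
  expect_identical(b2$truth$causal_marker, b$truth$causal_marker)
})

test_that("readings reader validates wells, duplicates and numeric ODs", {
  dir <- withr::local_tempdir()
  lay <- data.frame(well = "A01", strain = "N2", treatment = "ev",
                    replicate = 1, role = "sample")
  write_layout(lay, file.path(dir, "layout.csv"))
  layout <- read_layout(file.path(dir, "layout.csv"))

  # shuffled time order is sorted on read
  rd <- data.frame(well = "A01", time_h = c(48, 0, 24), od = c(0.4, 0.8, 0.6))
  write.csv(rd, file.path(dir, "readings.csv"), row.names = FALSE)
  curves <- read_readings(file.path(dir, "readings.csv"), layout)
  expect_equal(curves[["A01"]]$time_h, c(0, 24, 48))
  expect_equal(curves[["A01"]]$od, c(0.8, 0.6, 0.4))

  rd_bad <- rbind(rd, data.frame(well = "B02", time_h = 0, od = 0.7))
  write.csv(rd_bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_readings(file.path(dir, "bad.csv"), layout),
               "B02", class = "layout_error")

  rd_dup <- rbind(rd, rd[1, ])
  write.csv(rd_dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_readings(file.path(dir, "dup.csv"), layout),
               class = "format_error")

  rd_chr <- rd; rd_chr$od <- c("0.4", "x", "0.6")
  write.csv(rd_chr, file.path(dir, "chr.csv"), row.names = FALSE)
  expect_error(read_readings(file.path(dir, "chr.csv"), layout),
               class = "format_error")
})
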