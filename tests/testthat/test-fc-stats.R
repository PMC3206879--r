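test_that("signature matrix scores replicates against the pooled mean", {
  # two groups fully separated at every scored timepoint -> forced table
  a <- lapply(1:2, function(i) norm_curve(c(1, 0.9, 0.9, 0.9), well = paste0("A", i)))
  b <- lapply(1:2, function(i) norm_curve(c(1, 0.1, 0.1, 0.1), well = paste0("B", i)))
  m <- signature_matrix(a, b)
  expect_equal(unclass(m), rbind(group_a = c(0, 6), group_b = c(6, 0)),
               ignore_attr = TRUE)
  expect_equal(attr(m, "n_ties"), 0)

  # identical groups give identical rows
  m2 <- signature_matrix(a, a)
  expect_equal(m2[1, ], m2[2, ])

  # hand-scored oracle: pooled means at t=24,48 are 0.6 and 0.5
  a3 <- list(norm_curve(c(1, 0.9, 0.8)), norm_curve(c(1, 0.7, 0.6)))
  b3 <- list(norm_curve(c(1, 0.5, 0.4)), norm_curve(c(1, 0.3, 0.2)))
  m3 <- signature_matrix(a3, b3)
  expect_equal(unclass(m3), rbind(group_a = c(0, 4), group_b = c(4, 0)),
               ignore_attr = TRUE)

  bad <- norm_curve(c(1, 0.5), time_h = c(0, 48))
  expect_error(signature_matrix(a, list(bad)), class = "alignment_error")
  expect_error(signature_matrix(list(raw_curve(c(0.8, 0.6))), a),
               class = "state_error")
})

test_that("signature counts plus ties account for every observation", {
  set.seed(41)
  for (i in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1); tp <- sample(4:9, 1)
    mk <- function(n, pre) lapply(seq_len(n), function(j)
      norm_curve(c(1, round(runif(tp - 1), 1)), well = paste0(pre, j),
                 time_h = seq(0, by = 24, length.out = tp)))
    m <- signature_matrix(mk(na, "a"), mk(nb, "b"))
    expect_equal(sum(m) + attr(m, "n_ties"), (na + nb) * (tp - 1))
  }
})

test_that("chi-square matches the hand-computed expected-count oracle", {
  # reference table: expected counts [[21,15],[21,15]],
  # statistic = 2*81/21 + 2*81/15
  res <- chi_square_2x2(matrix(c(12, 30, 24, 6), 2))
  expect_equal(res$statistic, 2 * 81 / 21 + 2 * 81 / 15, tolerance = 1e-12)
  expect_equal(res$statistic, 18.514286, tolerance = 1e-6)
  expect_equal(res$p_value, pchisq(18.5142857142857, 1, lower.tail = FALSE))
  expect_lt(res$p_value, 2e-5)
  expect_equal(res$df, 1L)

  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p_value, 1)
  # perfect association: statistic equals N
  expect_equal(chi_square_2x2(matrix(c(5, 0, 0, 5), 2))$statistic, 10)
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2)),
               class = "degenerate_error")
  # swapping group rows leaves the statistic unchanged
  m <- matrix(c(12, 30, 24, 6), 2)
  expect_equal(chi_square_2x2(m[2:1, ])$statistic,
               chi_square_2x2(m)$statistic)
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(43)
  for (i in 1:50) {
    m <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(chi_square_2x2(m)$statistic,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Welch t-test on endpoints and slopes behaves across regimes", {
  mk <- function(ods, pre) lapply(seq_along(ods), function(i)
    norm_curve(c(1, 0.9, ods[i]), well = paste0(pre, i)))
  # identical groups: no difference
  g <- mk(c(0.5, 0.6, 0.55), "a")
  same <- fc_t_test(g, g, feature = "endpoint")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # strong endpoint separation; oracle = hand Welch formula
  a <- c(0.10, 0.11, 0.09); b <- c(0.80, 0.82, 0.78)
  res <- fc_t_test(mk(a, "a"), mk(b, "b"), feature = "endpoint")
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  # noise-free flat vs steep slopes: perfect separation floors the p-value
  flat <- lapply(1:3, function(i) norm_curve(rep(1, 9), well = paste0("f", i)))
  steep <- lapply(1:3, function(i)
    norm_curve(1 - 0.004 * seq(0, 192, 24), well = paste0("s", i)))
  res2 <- fc_t_test(flat, steep, feature = "slope", t_start = 24, t_end = 192)
  expect_gt(res2$p_value, 0)
  expect_equal(res2$p_value, 1e-300)

  expect_error(fc_t_test(g[1], g, feature = "endpoint"),
               class = "sample_size_error")
})

test_that("start-OD interaction is detected on raw data and shrinks after normalization", {
  # curves whose raw decline is proportional to their start OD (the
  # multiplicative structure the assay's normalization is designed to remove)
  set.seed(47)
  tp <- seq(0, 192, 24)
  starts <- rnorm(30, 0.83, 0.069)
  curves <- lapply(seq_along(starts), function(i) {
    od <- starts[i] * (1 - 0.004 * tp) + rnorm(length(tp), 0, 1e-4)
    raw_curve(abs(od), time_h = tp, well = paste0("W", i))
  })
  raw <- start_od_effect(curves, use_normalized = FALSE)
  nrm <- start_od_effect(curves, use_normalized = TRUE)
  expect_lt(raw$interaction_p, 1e-10)
  expect_equal(raw$interaction_effect, -0.004, tolerance = 0.2)
  expect_lt(abs(nrm$interaction_effect), abs(raw$interaction_effect))
  expect_gt(nrm$interaction_p, raw$interaction_p)

  same <- lapply(1:5, function(i)
    raw_curve(c(0.8, 0.7, 0.6), well = paste0("S", i)))
  expect_error(start_od_effect(same, use_normalized = FALSE),
               class = "collinearity_error")
  expect_error(start_od_effect(curves[1:2]), class = "parameter_error")
})

test_that("start-OD interaction test holds its nominal type-I rate", {
  # datasets with no start-OD dependence, generated under the fitted model
  set.seed(53)
  tp <- seq(0, 192, 24)
  reject <- replicate(200, {
    curves <- lapply(1:10, function(i) {
      od <- c(1, 1 - 0.004 * tp[-1] + rnorm(length(tp) - 1, 0, 0.01))
      norm_curve(od, time_h = tp, well = paste0("W", i),
                 start_od = rnorm(1, 0.83, 0.069))
    })
    start_od_effect(curves, use_normalized = TRUE)$interaction_p < 0.05
  })
  phat <- mean(reject)
  expect_lt(abs(phat - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})
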