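test_that("feature records are complete, reproducible, and consistent", {
  ds <- build_dataset1(lengths = 10L, n_per_length = 3L, seed = 7,
                       acn_dirs = 20L)
  expect_equal(nrow(ds$features), 3L)
  expect_true(all(ds$features$V_sphere >= ds$features$V_hull))
  expect_true(all(ds$features$I >= ds$features$M))
  expect_true(all(ds$features$num_bars >= 0))
  expect_equal(length(ds$curves), 3L)
  ds2 <- build_dataset1(lengths = 10L, n_per_length = 3L, seed = 7,
                        acn_dirs = 20L)
  expect_identical(ds$features, ds2$features)
})

test_that("typed dataset cells contain only the requested type", {
  ds <- build_dataset2(types = "0_1", lengths = 30L, n_per_cell = 4L,
                       seed = 11, acn_dirs = 10L)
  expect_equal(nrow(ds$features), 4L)
  expect_true(all(ds$features$type == "0_1"))
  expect_null(attr(ds, "incomplete"))
  # an exhausted budget yields an incomplete-cell report, not padding
  ds_bad <- build_dataset2(types = "6_3", lengths = 30L, n_per_cell = 2L,
                           seed = 12, max_attempts = 1L, acn_dirs = 10L)
  inc <- attr(ds_bad, "incomplete")
  expect_false(is.null(inc))
  expect_equal(inc$got, 0L)
})

test_that("correlation tables recover exact and planted relationships", {
  f <- data.frame(length = rep(c(10, 20), each = 50),
                  I = rep(1:50, 2))
  f$V_hull <- 2 * f$I + 1
  ct <- correlations_by_length(f, "I", "V_hull")
  expect_equal(ct$pearson, c(1, 1), tolerance = 1e-12)
  expect_equal(ct$spearman, c(1, 1), tolerance = 1e-12)
  f$V_hull <- -f$I^3  # strictly decreasing, nonlinear
  ct <- correlations_by_length(f, "I", "V_hull")
  expect_equal(ct$spearman, c(-1, -1), tolerance = 1e-12)
  # planted bivariate normal, r = -0.5: estimate within the Fisher-z band
  set.seed(19)
  n <- 500
  x <- rnorm(n)
  y <- -0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  ct <- correlations_by_length(data.frame(length = 1, I = x, V_hull = y),
                               "I", "V_hull")
  expect_lt(abs(ct$pearson + 0.5), 0.12)
  # undersized groups are skipped with a warning
  small <- data.frame(length = c(1, 1, 1, 1, 2, 2), I = rnorm(6),
                      V_hull = rnorm(6))
  expect_warning(ct <- correlations_by_length(small, "I", "V_hull"), "skipped")
  expect_equal(ct$group, 1)
  # all groups undersized: empty table, not an error
  tiny <- data.frame(length = c(1, 2), I = rnorm(2), V_hull = rnorm(2))
  ct0 <- suppressWarnings(correlations_by_length(tiny, "I", "V_hull"))
  expect_equal(nrow(ct0), 0L)
})

test_that("linear fits handle exact lines and degenerate responses", {
  lf <- linear_fit(1:10, 3 * (1:10) - 2)
  expect_equal(lf$slope, 3, tolerance = 1e-12)
  expect_equal(lf$intercept, -2, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)
  cf <- linear_fit(1:10, rep(2, 10))
  expect_true(cf$degenerate)
  expect_equal(cf$r_squared, 0)
})

test_that("split-half robustness: identical halves give zero discrepancy", {
  f <- data.frame(length = rep(c(10, 20), each = 40), I = rep(1:40, 2))
  f$V_hull <- 5 * f$I
  sh <- split_half_robustness(f, "I", "V_hull", seed = 3)
  expect_equal(sh$max_abs_diff, 0, tolerance = 1e-12)
  # planted-correlation data: halves agree within sampling variability
  set.seed(20)
  n <- 1000
  x <- rnorm(n)
  f2 <- data.frame(length = 1, I = x, V_hull = 0.6 * x + 0.8 * rnorm(n))
  sh2 <- split_half_robustness(f2, "I", "V_hull", seed = 4)
  expect_lt(sh2$max_abs_diff, 0.15)
})

test_that("per-cell averages track the cell curves", {
  ds <- build_dataset2(types = "0_1", lengths = c(20L, 30L), n_per_cell = 3L,
                       seed = 21, acn_dirs = 10L)
  av <- average_summaries(ds)
  expect_equal(nrow(av), 2L)
  expect_equal(av$n, c(3L, 3L))
  expect_true(all(av$curve_max_value > 0))
  expect_equal(av$mean_I,
               vapply(c(20L, 30L), function(n) mean(ds$features$I[ds$features$length == n]),
                      numeric(1)))
})
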