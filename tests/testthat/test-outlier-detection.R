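# Median-z and perpendicular-distance outlier calls.

test_that("median z-scores follow the median-centered, full-sd formula", {
  expect_equal(median_z_scores(rep(0.5, 5)), rep(0, 5))
  v <- c(0.49, 0.50, 0.51, 0.50, 0.80)
  z <- median_z_scores(v)
  # closed form: median 0.50, sd around the mean 0.134350
  expect_equal(z[5], (0.80 - 0.50) / sd(v), tolerance = 1e-12)
  expect_equal(z[5], 2.2330, tolerance = 1e-4)
  # masking: the outlier inflates the sd it is judged against
  base <- c(0.50, 0.49, 0.51, 0.50, 0.50, 0.51, 0.49)
  shifted <- c(base, tail(base, 1) + 3 * sd(base))
  z2 <- median_z_scores(shifted)
  expect_lt(abs(z2[length(z2)]), 3)
  expect_gt(abs(z2[length(z2)]), 1.5)
  # NA preserved in place; too-few values is an error
  expect_true(is.na(median_z_scores(c(0.1, NA, 0.2, 0.3))[2]))
  expect_error(median_z_scores(c(0.1, 0.2)), ">= 3")
})

test_that("perpendicular distance matches the closed form and is endpoint-symmetric", {
  l <- mixing_line("LRP1B_AF", "ERBB4_AF", c(0, 0), c(0.25, 0.33))
  mid <- (c(0, 0) + c(0.25, 0.33)) / 2
  expect_equal(perpendicular_distance(mid, l)$distance, 0, tolerance = 1e-12)
  d <- perpendicular_distance(c(0.25, 0), l)
  expect_equal(d$distance, 0.33 / sqrt(1.32^2 + 1), tolerance = 1e-6)
  expect_equal(d$distance, 0.1993, tolerance = 1e-3)
  expect_lt(d$signed, 0)   # below the line: deficient
  l_swap <- mixing_line("LRP1B_AF", "ERBB4_AF", c(0.25, 0.33), c(0, 0))
  set.seed(3)
  pts <- cbind(runif(20, 0, 0.3), runif(20, 0, 0.5))
  expect_equal(perpendicular_distance(pts, l)$signed,
               perpendicular_distance(pts, l_swap)$signed)
  expect_error(mixing_line("a", "b", c(0, 0), c(0, 0)), "differ")
})

test_that("clean two-subclone panels are never flagged", {
  sim <- sim_panel(seed = 4, sigma_af = 0, sigma_cn = 0, n = 60)
  oc <- classify_outliers(sim$table)
  expect_identical(oc$n_flagged, 0L)
  expect_identical(oc$max_dimensions, 0L)
  # stable truncal markers are constant: sd = 0 convention, z all zero
  expect_true(all(oc$z == 0))
})

test_that("a single displaced sample is flagged in exactly its dimension with direction", {
  sim <- sim_panel(seed = 5, sigma_af = 0, sigma_cn = 0, n = 101)
  tab <- sim$table
  tab$values[7, "ERBB4_AF"] <- tab$values[7, "ERBB4_AF"] + 0.15
  oc <- classify_outliers(tab)
  expect_identical(oc$n_flagged, 1L)
  expect_identical(unname(oc$dimensions_per_sample[7]), 1L)
  expect_identical(unname(oc$calls[7, "ERBB4_AF"]), 1L)   # excess
  expect_identical(oc$n_patterns, 1L)
  # confirm with the distance oracle that the displacement clears 0.07
  l <- default_mixing_lines()[[1]]
  d <- perpendicular_distance(tab$values[7, c("LRP1B_AF", "ERBB4_AF")], l)
  expect_gt(d$distance, 0.07)
  # deficient direction for the opposite sign
  tab$values[7, "ERBB4_AF"] <- tab$values[7, "ERBB4_AF"] - 0.30
  oc2 <- classify_outliers(tab)
  expect_identical(unname(oc2$calls[7, "ERBB4_AF"]), -1L)
})

test_that("thresholds are strict and missing values are never flagged", {
  # flat line at y = 0.25: distance is |y - 0.25|
  panel <- marker_panel(c("X_AF", "Y_AF"), c("X", "Y"), "AF")
  # exactly representable values so the boundary case is exact in binary
  vals <- matrix(c(0.05, 0.10, 0.15, 0.20,
                   0.3125, 0.25, 0.25, NA), ncol = 2,
                 dimnames = list(paste0("s", 1:4), c("X_AF", "Y_AF")))
  tab <- measurement_table(vals, panel)
  flat <- mixing_line("X_AF", "Y_AF", c(0, 0.25), c(0.25, 0.25))
  oc <- classify_outliers(tab, stable_markers = character(0),
                          mixing_lines = list(flat), d_threshold = 0.0625)
  expect_identical(unname(oc$calls[, "Y_AF"]), c(0L, 0L, 0L, NA))  # D at threshold
  vals[1, "Y_AF"] <- 0.3130
  oc2 <- classify_outliers(measurement_table(vals, panel),
                           stable_markers = character(0),
                           mixing_lines = list(flat), d_threshold = 0.0625)
  expect_identical(unname(oc2$calls[, "Y_AF"]), c(1L, 0L, 0L, NA))
})

test_that("flag decisions are invariant under sample reordering", {
  sim <- sim_panel(seed = 6, n = 80, uniform = FALSE,
                   outlier_rate = 0.15)
  oc <- classify_outliers(sim$table)
  perm <- sample(nrow(sim$table$values))
  tab2 <- sim$table
  tab2$values <- tab2$values[perm, , drop = FALSE]
  tab2$samples <- tab2$samples[perm, , drop = FALSE]
  oc2 <- classify_outliers(tab2)
  expect_identical(oc2$calls, oc$calls[perm, , drop = FALSE])
  expect_identical(oc2$n_flagged, oc$n_flagged)
  expect_identical(oc2$n_patterns, oc$n_patterns)
})

test_that("pattern and source summaries count flagged samples correctly", {
  sim <- sim_panel(seed = 8, n = 120, uniform = FALSE,
                   outlier_rate = 0.2, crpc_fraction = 0.25)
  oc <- classify_outliers(sim$table)
  expect_identical(oc$n_flagged,
                   sum(oc$dimensions_per_sample > 0))
  expect_true(oc$n_patterns <= oc$n_flagged || oc$n_flagged == 0L)
  expect_true(all(names(oc$flagged_by_source) %in% c("crpc", "xenograft")))
})
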