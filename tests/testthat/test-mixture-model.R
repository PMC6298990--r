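g <- default_genotypes()

test_that("expected copy number is the affine mixture of subclone copy numbers", {
  expect_equal(expected_copy_number(0, g$subclone1, g$subclone2, "LRP1B"), 2)
  expect_equal(expected_copy_number(1, g$subclone1, g$subclone2, "LRP1B"), 4)
  expect_equal(expected_copy_number(0.7, g$subclone1, g$subclone2, "LRP1B"), 3.4)
  # uses mean_cn where present
  expect_equal(expected_copy_number(1, g$subclone1, g$subclone2, "ERBB4"), 2.8)
  expect_equal(expected_copy_number(0, g$subclone1, g$subclone2, "ERBB4"), 1.3)
  expect_error(expected_copy_number(0.5, g$subclone1, g$subclone2, "NOPE"),
               "not in genotype")
})

test_that("expected allele frequency is the exact template-ratio mixture", {
  expect_equal(expected_allele_frequency(1, g$subclone1, g$subclone2, "LRP1B"),
               0.25)
  expect_equal(expected_allele_frequency(0, g$subclone1, g$subclone2, "LRP1B"),
               0)
  expect_equal(expected_allele_frequency(0.5, g$subclone1, g$subclone2, "LRP1B"),
               0.5 / 3)
  # pure-subclone endpoints reproduce the published mixing-line endpoints
  ends <- list(ERBB4 = c(0.33, 0), MET = c(0.5, 0.67), SAAL1 = c(0.4, 0.25))
  for (gene in names(ends)) {
    expect_lt(abs(expected_allele_frequency(1, g$subclone1, g$subclone2, gene) -
                    ends[[gene]][1]), 0.01)
    expect_lt(abs(expected_allele_frequency(0, g$subclone1, g$subclone2, gene) -
                    ends[[gene]][2]), 0.01)
  }
  # zero mixed copy number is an error
  z1 <- subclone_genotype("X", 0, 1, mean_cn = 0)
  expect_error(
    expected_allele_frequency(0.5, z1, z1, "X", denominator = "mean_cn"),
    "zero")
})

test_that("mixture predictions stay in range and CN is monotone in p", {
  set.seed(42)
  p_grid <- seq(0, 1, by = 0.05)
  for (rep in 1:25) {
    t1 <- sample(1:8, 1); m1 <- sample(0:t1, 1)
    t2 <- sample(1:8, 1); m2 <- sample(0:t2, 1)
    a <- subclone_genotype("L", m1, t1)
    b <- subclone_genotype("L", m2, t2)
    af <- expected_allele_frequency(p_grid, a, b, "L")
    cn <- expected_copy_number(p_grid, a, b, "L")
    expect_true(all(af >= 0 & af <= 1))
    expect_true(all(cn >= 0))
    if (t1 > t2) expect_true(all(diff(cn) > 0))
    # affine in p: second differences vanish
    expect_equal(max(abs(diff(diff(cn)))), 0, tolerance = 1e-12)
  }
})

test_that("integer genotype calls match the homogeneous-sample worked examples", {
  cases <- list(list(0.33, 2.9, 1L, 3L), list(0.48, 2.00, 1L, 2L),
                list(0.66, 2.86, 2L, 3L), list(0.99, 3.01, 3L, 3L),
                list(0.50, 4.01, 2L, 4L), list(0.0, 2.0, 0L, 2L))
  for (cs in cases) {
    call <- call_integer_genotype(cs[[1]], cs[[2]])
    expect_identical(call$m, cs[[3]])
    expect_identical(call$t, cs[[4]])
    expect_lt(call$residual, 0.5 / call$t + 1e-12)
  }
  # ties break toward fewer mutant copies
  expect_identical(call_integer_genotype(0.25, 2)$m, 0L)
  expect_error(call_integer_genotype(0.5, 0.4), "cn")
  expect_error(call_integer_genotype(1.2, 2), "af")
})

test_that("genotype calls round-trip exactly and agree with exhaustive search", {
  for (t in 1:8) {
    for (m in 0:t) {
      call <- call_integer_genotype(m / t, t)
      expect_identical(c(call$m, call$t), c(m, t))
    }
  }
  # independent oracle: enumerate all m for T = round(cn)
  set.seed(7)
  for (i in 1:1000) {
    af <- runif(1); cn <- runif(1, 0.6, 8.4)
    call <- call_integer_genotype(af, cn)
    t_or <- max(1L, as.integer(round(cn)))
    best <- Inf; m_or <- NA_integer_
    for (m in 0:t_or) {
      d <- abs(af - m / t_or)
      if (d < best) { best <- d; m_or <- m }
    }
    expect_identical(call$t, t_or)
    expect_identical(call$m, m_or)
  }
})

test_that("line fits report OLS slope and exact-t correlation p-values", {
  fit <- fit_marker_pair(1:5, 2 * (1:5))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  x <- c(0, 1, 2, 3); y <- c(1, 2, 2, 4)
  fit <- fit_marker_pair(x, y)
  expect_equal(fit$slope, 0.9)
  expect_equal(fit$r, 4.5 / sqrt(5 * 4.75), tolerance = 1e-12)
  ct <- cor.test(x, y)                       # independent check of r and p
  expect_equal(fit$r, unname(ct$estimate))
  expect_equal(fit$p_value, ct$p.value)
  expect_error(fit_marker_pair(x, rep(1, 4)), "variance")
  expect_error(fit_marker_pair(c(1, 2), c(1, 2)), "3")
})

test_that("cellularity uncertainty doubles the AF uncertainty", {
  expect_equal(cellularity_uncertainty(0.011), 0.022)
  expect_equal(cellularity_uncertainty(0), 0)
  expect_equal(cellularity_uncertainty(0.015), 0.030)
})

test_that("integer deviation measures distance to the nearest copy integer", {
  expect_equal(integer_deviation(2.8), 0.2)
  expect_equal(integer_deviation(1.3), 0.3)
  expect_equal(integer_deviation(4.0), 0)
  expect_true(all(integer_deviation(runif(50, 0, 8)) <= 0.5))
})

test_that("mixing fractions interpolate the anchor CN and clip to [0, 1]", {
  p <- estimate_mixing_fraction(3.4, g$subclone1, g$subclone2, "LRP1B")
  expect_equal(p, 0.7)
  expect_equal(estimate_mixing_fraction(2.0, g$subclone1, g$subclone2, "LRP1B"), 0)
  expect_equal(estimate_mixing_fraction(4.2, g$subclone1, g$subclone2, "LRP1B"), 1)
  expect_error(estimate_mixing_fraction(2, g$subclone1, g$subclone1, "EXOC4"),
               "uninformative")
})
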