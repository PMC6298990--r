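# Cohort-level correlation, differential and association statistics.

test_that("correlation matrix handles identical, negated and degenerate columns", {
  panel <- marker_panel(c("A_CN", "B_CN", "C_CN", "D_CN"), c("A", "B", "C", "D"),
                        "CN")
  set.seed(10)
  a <- runif(12, 1, 4)
  vals <- cbind(A_CN = a, B_CN = a, C_CN = max(a) + 0.5 - a,
                D_CN = rep(2, 12))
  rownames(vals) <- paste0("s", 1:12)
  tab <- measurement_table(vals, panel)
  cm <- correlation_matrix(tab)
  expect_equal(cm$r["A_CN", "B_CN"], 1)
  expect_equal(cm$r["A_CN", "C_CN"], -1)
  expect_true(is.na(cm$r["A_CN", "D_CN"]))     # zero variance
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r))
})

test_that("pairwise and complete-case modes agree when nothing is missing", {
  sim <- sim_panel(seed = 11, n = 30)
  cc <- correlation_matrix(sim$table, mode = "complete_case")
  pw <- correlation_matrix(sim$table, mode = "pairwise")
  expect_equal(cc$r, pw$r)
  expect_equal(cc$p_value, pw$p_value)
})

test_that("simulated panels reproduce the subclone-1 block structure", {
  sim <- simulate_two_subclone_panel(simulation_config(seed = 12))
  cm <- correlation_matrix(sim$table)
  expect_gt(cm$r["ERBB4_CN", "LRP1B_CN"], 0.7)
  expect_lt(cm$r["AR_CN", "LRP1B_CN"], -0.4)
  block <- c("ERBB4_CN", "LRP1B_CN", "EPHA3_CN", "EPHA5_CN", "PTPRD_CN")
  sub <- cm$r[block, block]
  expect_true(all(sub[upper.tri(sub)] > 0))
})

test_that("Welch cohort tests are symmetric, BH-monotone and power-consistent", {
  sim <- simulate_two_subclone_panel(simulation_config(seed = 13))
  res <- suppressWarnings(cohort_differential_tests(sim$table,
                                                    pool_cisplatin = TRUE))
  # q never below p, and BH never rejects more than unadjusted p would
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  for (k in unique(res$assay_kind)) {
    sub <- res[res$assay_kind == k, ]
    expect_lte(sum(sub$q_value <= 0.05), sum(sub$p_value <= 0.05))
    # q monotone non-decreasing in p rank
    expect_true(all(diff(sub$q_value[order(sub$p_value)]) >= -1e-12))
  }
  # the cisplatin-depleted subclone-1 marker separates cohorts
  anchor <- res[res$marker_id == "LRP1B_CN" &
                  ((res$cohort_a == "cisplatin" & res$cohort_b == "vehicle") |
                   (res$cohort_a == "vehicle" & res$cohort_b == "cisplatin")), ]
  expect_true(nrow(anchor) == 1 && anchor$q_value < 0.05)
  # symmetry in cohort order: t negates, p identical (direct check)
  v <- sim$table$values[, "LRP1B_CN"]
  trt <- sim$table$samples$treatment
  t_ab <- t.test(v[trt == "cisplatin"], v[trt == "vehicle"])
  t_ba <- t.test(v[trt == "vehicle"], v[trt == "cisplatin"])
  expect_equal(unname(t_ab$statistic), -unname(t_ba$statistic))
  expect_equal(t_ab$p.value, t_ba$p.value)
})

test_that("identically distributed cohorts give t = 0, p = 1 on shared data", {
  panel <- marker_panel("A_CN", "A", "CN")
  vals <- matrix(rep(c(1.7, 2.4, 3.1, 2.0), 2), ncol = 1,
                 dimnames = list(paste0("s", 1:8), "A_CN"))
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     treatment = rep(c("vehicle", "cisplatin"), each = 4))
  tab <- measurement_table(vals, panel, samples = meta)
  res <- cohort_differential_tests(tab)
  expect_equal(res$welch_t, 0)
  expect_equal(res$p_value, 1)
})

test_that("volume association recovers the cisplatin coupling and nulls", {
  # n = 15 cisplatin samples per replicate: judge the typical fit across
  # replicates, not one draw
  fits <- lapply(1:10, function(s) {
    sim <- simulate_two_subclone_panel(simulation_config(seed = s))
    volume_association(sim$table, "LRP1B_CN")
  })
  expect_gt(median(sapply(fits, `[[`, "r")), 0.6)
  expect_gte(sum(sapply(fits, `[[`, "p_value") < 0.05), 7)
  sim <- simulate_two_subclone_panel(simulation_config(seed = 14))
  # no coupling outside cisplatin: p rarely small across replicates
  small_p <- 0
  for (s in 1:20) {
    simn <- simulate_two_subclone_panel(simulation_config(seed = 100 + s))
    fitn <- volume_association(simn$table, "LRP1B_CN",
                               cohorts = c("vehicle", "docetaxel"))
    small_p <- small_p + (fitn$p_value < 0.05)
  }
  expect_lte(small_p, 4)
  # perfectly linear volumes give r = 1
  tab <- sim$table
  tab$samples$volume_change_pct <- 10 * tab$values[, "LRP1B_CN"] - 30
  expect_equal(volume_association(tab, "LRP1B_CN", cohorts = NULL)$r, 1)
  # fewer than 3 usable samples in the filtered cohort is an error
  # naming the cohort
  tab2 <- sim$table
  tab2$samples$volume_change_pct[tab2$samples$treatment == "doxorubicin"][1:2] <-
    NA
  expect_error(volume_association(tab2, "LRP1B_CN", cohorts = "doxorubicin"),
               "doxorubicin")
})

test_that("cohort prevalences average the mixing fractions per group", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     treatment = c("vehicle", "vehicle", "cisplatin",
                                   "cisplatin_retreat", "none", "docetaxel"))
  p <- setNames(c(0.7, 0.7, 0.4, 0.46, 0.7, 0.7), meta$sample_id)
  prev <- prevalence_by_cohort(p, meta)
  expect_equal(unname(prev["cisplatin"]), 0.43)
  expect_equal(unname(prev["non_cisplatin"]), 0.7)
  by_arm <- prevalence_by_cohort(p, meta, grouping = "treatment")
  expect_false("doxorubicin" %in% names(by_arm))  # empty cohort omitted
  # simulated selection panel: recovered cohort means close to the truth
  sim <- simulate_two_subclone_panel(simulation_config(seed = 15))
  g <- default_genotypes()
  p_hat <- estimate_fractions(sim$table, g$subclone1, g$subclone2)
  prev2 <- prevalence_by_cohort(p_hat, sim$metadata)
  true_prev <- tapply(sim$truth$p_true,
                      ifelse(sim$truth$treatment %in%
                               c("cisplatin", "cisplatin_retreat"),
                             "cisplatin", "non_cisplatin"), mean)
  expect_equal(unname(prev2["cisplatin"]), unname(true_prev["cisplatin"]),
               tolerance = 0.05)
  expect_equal(unname(prev2["non_cisplatin"]),
               unname(true_prev["non_cisplatin"]), tolerance = 0.05)
})
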