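# End-to-end pipeline: validate -> subclone endpoints -> integer
# genotypes -> per-sample mixing fractions -> bottleneck outliers ->
# cohort statistics, with CSV outputs and a plain-text summary.

#' Run the full deconstruction pipeline
#'
#' Sequences every analysis stage on one measurement table and writes
#' \code{genotypes.csv}, \code{fractions.csv}, \code{outliers.csv},
#' \code{tests.csv}, \code{corr.csv} and \code{summary.md} into
#' \code{out_dir}. Any stage error aborts with the stage name and cause,
#' and partial outputs written by this call are removed.
#'
#' @param table a \code{\link{measurement_table}} with sample metadata,
#'   or a path to a measurements CSV (then \code{panel} and
#'   \code{metadata} paths are required).
#' @param out_dir output directory (created if absent).
#' @param panel optional \code{\link{marker_panel}} or panel config
#'   path, used when \code{table} is a file path.
#' @param metadata optional metadata \code{data.frame} or CSV path.
#' @param anchor anchor AF marker id (default \code{"LRP1B_AF"}).
#' @param anchor_values anchor AF endpoints (default \code{c(0.25, 0)}).
#' @param anchor_gene gene of the anchor CN assays (default
#'   \code{"LRP1B"}).
#' @param stable_markers,mixing_lines,z_threshold,d_threshold passed to
#'   \code{\link{classify_outliers}}.
#' @param alpha significance level for cohort tests (default 0.05).
#' @param correlation_markers markers for the correlation matrix
#'   (default: all).
#' @return Invisibly, a list with every stage result (\code{endpoints},
#'   \code{genotypes}, \code{fractions}, \code{outliers}, \code{tests},
#'   \code{correlations}, \code{prevalence}, \code{files}).
#' @export
run_full_pipeline <- function(table, out_dir,
                              panel = NULL, metadata = NULL,
                              anchor = "LRP1B_AF", anchor_values = c(0.25, 0),
                              anchor_gene = "LRP1B",
                              stable_markers = c("BRCA2_AF", "PTCH1_AF",
                                                 "TP53_AF", "CSMD3_AF"),
                              mixing_lines = default_mixing_lines(),
                              z_threshold = 3, d_threshold = 0.07,
                              alpha = 0.05, correlation_markers = NULL) {
  written <- character(0)
  stage <- "input"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (is.character(table)) {
      if (is.character(panel)) panel <- read_panel_config(panel)
      if (is.null(panel)) stop("panel required when reading from file")
      if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
      table <- read_measurements(table, panel, metadata = metadata)
    } else if (!is.null(metadata)) {
      if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
      table <- measurement_table(table$values, table$panel, samples = metadata)
    }
    stopifnot(inherits(table, "measurement_table"))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    emit <- function(df, name) {
      f <- file.path(out_dir, name)
      utils::write.csv(df, f, row.names = FALSE, na = "")
      written <<- c(written, f)
      f
    }

    stage <- "endpoints"
    endpoints <- infer_subclone_endpoints(table, anchor = anchor,
                                          anchor_values = anchor_values)
    stage <- "genotypes"
    geno <- genotype_subclones(endpoints)
    emit(geno$calls, "genotypes.csv")

    stage <- "fractions"
    fractions <- estimate_fractions(table, geno$subclone1, geno$subclone2,
                                    anchor_gene = anchor_gene)
    emit(data.frame(sample_id = names(fractions),
                    mixing_fraction = unname(fractions)), "fractions.csv")

    stage <- "outliers"
    outliers <- classify_outliers(table, stable_markers = stable_markers,
                                  mixing_lines = mixing_lines,
                                  z_threshold = z_threshold,
                                  d_threshold = d_threshold)
    out_df <- data.frame(sample_id = rownames(outliers$calls),
                         as.data.frame(outliers$calls),
                         n_dimensions = outliers$dimensions_per_sample,
                         pattern = outliers$patterns,
                         check.names = FALSE)
    emit(out_df[outliers$dimensions_per_sample > 0, , drop = FALSE],
         "outliers.csv")

    stage <- "cohort_tests"
    tests <- NULL
    if (!is.null(table$samples) && "treatment" %in% names(table$samples) &&
        length(unique(stats::na.omit(table$samples$treatment))) >= 2) {
      tests <- suppressWarnings(cohort_differential_tests(table, alpha = alpha))
      emit(tests, "tests.csv")
    }

    stage <- "correlations"
    corr <- correlation_matrix(table, markers = correlation_markers)
    emit(data.frame(marker_id = rownames(corr$r), corr$r,
                    check.names = FALSE), "corr.csv")

    stage <- "prevalence"
    prevalence <- NULL
    if (!is.null(table$samples) && "treatment" %in% names(table$samples)) {
      prevalence <- prevalence_by_cohort(fractions, table$samples)
    }

    stage <- "summary"
    f <- file.path(out_dir, "summary.md")
    .write_summary(f, table, geno, fractions, outliers, tests, corr,
                   prevalence, anchor, anchor_values,
                   z_threshold, d_threshold, alpha)
    written <- c(written, f)

    invisible(list(endpoints = endpoints, genotypes = geno,
                   fractions = fractions, outliers = outliers,
                   tests = tests, correlations = corr,
                   prevalence = prevalence, files = written))
  }, error = on_fail)
}

.write_summary <- function(path, table, geno, fractions, outliers, tests,
                           corr, prevalence, anchor, anchor_values,
                           z_threshold, d_threshold, alpha) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# Subclone deconstruction summary")
  w("")
  w(sprintf("- samples: %d, markers: %d (%d AF, %d CN)",
            nrow(table$values), ncol(table$values),
            sum(table$panel$assay_kind == "AF"),
            sum(table$panel$assay_kind == "CN")))
  w(sprintf("- anchor: %s at subclone AF endpoints (%.3g, %.3g)",
            anchor, anchor_values[1], anchor_values[2]))
  w(sprintf("- thresholds: |z| > %.3g, D > %.3g, alpha = %.3g",
            z_threshold, d_threshold, alpha))
  w("")
  w("## Subclone genotypes (2 subclones)")
  w("")
  w("gene | subclone1 m/T (mean CN) | subclone2 m/T (mean CN) | assumed T=2")
  w("---- | ----------------------- | ----------------------- | -----------")
  cl <- geno$calls
  for (i in seq_len(nrow(cl))) {
    w(sprintf("%s | %s/%s (%.2f) | %s/%s (%.2f) | %s",
              cl$gene[i], cl$m1[i], cl$t1[i],
              ifelse(is.na(cl$cn_endpoint1[i]), as.numeric(cl$t1[i]),
                     cl$cn_endpoint1[i]),
              cl$m2[i], cl$t2[i],
              ifelse(is.na(cl$cn_endpoint2[i]), as.numeric(cl$t2[i]),
                     cl$cn_endpoint2[i]),
              cl$assumed_t2[i]))
  }
  w("")
  if (!is.null(prevalence) && length(prevalence)) {
    w("## Mean subclone-1 prevalence by cohort")
    w("")
    for (nm in names(prevalence)) w(sprintf("- %s: %.3f", nm, prevalence[nm]))
    w("")
  }
  w("## Outliers")
  w("")
  w(sprintf("- flagged samples: %d of %d", outliers$n_flagged,
            nrow(outliers$calls)))
  w(sprintf("- max dimensions per sample: %d", outliers$max_dimensions))
  w(sprintf("- distinct deviation patterns: %d", outliers$n_patterns))
  if (!is.null(outliers$flagged_by_source)) {
    for (nm in names(outliers$flagged_by_source)) {
      w(sprintf("- flagged fraction (%s): %.3f", nm,
                outliers$flagged_by_source[nm]))
    }
  }
  w("")
  if (!is.null(tests)) {
    w("## Cohort differential tests")
    w("")
    w(sprintf("- significant at q <= %.3g: %d of %d", alpha,
              sum(tests$significant), nrow(tests)))
    top <- utils::head(tests, 3)
    for (i in seq_len(nrow(top))) {
      w(sprintf("- %s %s vs %s: t = %.2f, q = %.3g", top$marker_id[i],
                top$cohort_a[i], top$cohort_b[i], top$welch_t[i],
                top$q_value[i]))
    }
    w("")
  }
  rr <- corr$r; diag(rr) <- NA
  if (any(is.finite(rr))) {
    hi <- which(abs(rr) == max(abs(rr), na.rm = TRUE), arr.ind = TRUE)[1, ]
    w("## Headline correlation")
    w("")
    w(sprintf("- strongest pair: %s vs %s, r = %.3f",
              rownames(rr)[hi[1]], colnames(rr)[hi[2]], rr[hi[1], hi[2]]))
  }
  invisible(path)
}
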