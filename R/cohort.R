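# Cohort-level selection and association statistics.

#' Pairwise Pearson correlation matrix over markers
#'
#' Pearson r per marker pair with two-sided p-values from the t transform
#' on n - 2 degrees of freedom. \code{mode = "complete_case"} (default)
#' first restricts to samples with data for all requested markers, so
#' every pair uses the same n; \code{"pairwise"} uses all complete pairs
#' per marker pair. Zero-variance markers yield \code{NA} for their pairs.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param markers marker ids to include (default all).
#' @param mode \code{"complete_case"} or \code{"pairwise"}.
#' @return A list of class \code{"correlation_matrix"}: square matrices
#'   \code{r}, \code{p_value}, \code{n} (markers x markers).
#' @export
correlation_matrix <- function(table, markers = NULL,
                               mode = c("complete_case", "pairwise")) {
  stopifnot(inherits(table, "measurement_table"))
  mode <- match.arg(mode)
  if (is.null(markers)) markers <- colnames(table$values)
  vals <- table$values[, markers, drop = FALSE]
  if (mode == "complete_case") {
    vals <- vals[rowSums(is.na(vals)) == 0L, , drop = FALSE]
  }
  k <- length(markers)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  n <- matrix(0L, k, k, dimnames = list(markers, markers))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- is.finite(vals[, i]) & is.finite(vals[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (i == j) { r[i, j] <- 1; p[i, j] <- NA_real_; next }
      if (nij < 3L) next
      if (stats::sd(vals[ok, i]) == 0 || stats::sd(vals[ok, j]) == 0) next
      fit <- fit_marker_pair(vals[ok, i], vals[ok, j])
      r[i, j] <- r[j, i] <- fit$r
      p[i, j] <- p[j, i] <- fit$p_value
    }
  }
  structure(list(r = r, p_value = p, n = n, mode = mode),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s) over %d markers\n", x$mode, ncol(x$r)))
  print(round(x$r, 2))
  invisible(x)
}

#' Welch tests of every marker between every pair of treatment cohorts
#'
#' For each marker and each unordered pair of cohorts with at least 2
#' samples carrying that marker, performs Welch's unequal-variance t-test
#' and applies Benjamini-Hochberg correction. By default AF markers and
#' CN markers form separate BH families (\code{families = "separate"});
#' \code{"pooled"} corrects across all tests at once.
#'
#' @param table a \code{\link{measurement_table}} whose samples carry a
#'   \code{treatment} column (or supply \code{metadata}).
#' @param metadata optional metadata \code{data.frame} overriding the
#'   table's.
#' @param alpha significance level for the \code{significant} flag on
#'   q-values (default 0.05).
#' @param families \code{"separate"} (default) or \code{"pooled"}.
#' @param pool_cisplatin if \code{TRUE}, cisplatin and cisplatin_retreat
#'   are merged into one "cisplatin" cohort before testing.
#' @return A \code{data.frame} sorted by q-value with columns
#'   \code{marker_id}, \code{assay_kind}, \code{cohort_a},
#'   \code{cohort_b}, \code{n_a}, \code{n_b}, \code{welch_t},
#'   \code{p_value}, \code{q_value}, \code{significant}.
#' @export
cohort_differential_tests <- function(table, metadata = NULL, alpha = 0.05,
                                      families = c("separate", "pooled"),
                                      pool_cisplatin = FALSE) {
  stopifnot(inherits(table, "measurement_table"))
  families <- match.arg(families)
  meta <- if (is.null(metadata)) table$samples else
    metadata[match(rownames(table$values), metadata$sample_id), , drop = FALSE]
  if (is.null(meta) || !"treatment" %in% names(meta)) {
    stop("treatment metadata required")
  }
  trt <- meta$treatment
  if (pool_cisplatin) trt[trt == "cisplatin_retreat"] <- "cisplatin"
  cohorts <- sort(unique(trt[!is.na(trt)]))
  rows <- list()
  for (mk in colnames(table$values)) {
    v <- table$values[, mk]
    for (a_i in seq_along(cohorts)) {
      for (b_i in seq_along(cohorts)) {
        if (b_i <= a_i) next
        va <- v[!is.na(trt) & trt == cohorts[a_i] & !is.na(v)]
        vb <- v[!is.na(trt) & trt == cohorts[b_i] & !is.na(v)]
        if (length(va) < 2L || length(vb) < 2L) {
          warning(sprintf("skipping %s: cohort pair %s/%s has < 2 samples",
                          mk, cohorts[a_i], cohorts[b_i]), call. = FALSE)
          next
        }
        tt <- tryCatch(stats::t.test(va, vb, var.equal = FALSE),
                       error = function(e) NULL)  # fails if both constant
        if (is.null(tt)) next
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = mk,
          assay_kind = table$panel$assay_kind[match(mk, table$panel$marker_id)],
          cohort_a = cohorts[a_i], cohort_b = cohorts[b_i],
          n_a = length(va), n_b = length(vb),
          welch_t = unname(tt$statistic), p_value = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable marker/cohort pairs")
  res <- do.call(rbind, rows)
  if (families == "pooled") {
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  } else {
    res$q_value <- NA_real_
    for (k in unique(res$assay_kind)) {
      sel <- res$assay_kind == k
      res$q_value[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
    }
  }
  res$significant <- res$q_value <= alpha
  res <- res[order(res$q_value, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Association between a marker and tumor volume change
#'
#' OLS of % volume change on the marker value within a treatment cohort,
#' with Pearson r and two-sided p (t transform). Cisplatin and
#' cisplatin_retreat samples are pooled when \code{cohorts} includes
#' either by default.
#'
#' @param table a \code{\link{measurement_table}} with sample metadata
#'   carrying \code{treatment} and \code{volume_change_pct} (or supply
#'   \code{metadata}).
#' @param marker marker id (e.g. the anchor CN assay).
#' @param cohorts treatments to include (default
#'   \code{c("cisplatin", "cisplatin_retreat")}); \code{NULL} uses all
#'   samples.
#' @param metadata optional metadata \code{data.frame}.
#' @return A \code{\link{fit_marker_pair}} \code{"line_fit"} (volume on
#'   marker).
#' @export
volume_association <- function(table, marker,
                               cohorts = c("cisplatin", "cisplatin_retreat"),
                               metadata = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  meta <- if (is.null(metadata)) table$samples else
    metadata[match(rownames(table$values), metadata$sample_id), , drop = FALSE]
  if (is.null(meta) || !"volume_change_pct" %in% names(meta)) {
    stop("volume_change_pct metadata required")
  }
  if (!marker %in% colnames(table$values)) stop("unknown marker: ", marker)
  keep <- rep(TRUE, nrow(table$values))
  if (!is.null(cohorts)) {
    if (!"treatment" %in% names(meta)) stop("treatment metadata required")
    keep <- !is.na(meta$treatment) & meta$treatment %in% cohorts
  }
  x <- table$values[keep, marker]
  y <- meta$volume_change_pct[keep]
  n_ok <- sum(is.finite(x) & is.finite(y))
  if (n_ok < 3L) {
    stop(sprintf("only %d usable samples for marker %s in cohort(s) %s",
                 n_ok, marker,
                 if (is.null(cohorts)) "all" else paste(cohorts, collapse = "+")))
  }
  fit_marker_pair(x, y)
}

#' Mean subclone-1 prevalence per cohort
#'
#' Arithmetic mean of the per-sample mixing fractions within each cohort.
#' With \code{grouping = "cisplatin_vs_not"} (default) the cisplatin and
#' cisplatin-retreat arms form one "cisplatin" group and all other
#' treatments form "non_cisplatin"; \code{"treatment"} keeps each arm
#' separate. Cohorts with no fraction available are omitted.
#'
#' @param fractions named numeric vector of mixing fractions (names are
#'   sample ids), e.g. from \code{\link{estimate_fractions}}.
#' @param metadata metadata \code{data.frame} with \code{sample_id} and
#'   \code{treatment}.
#' @param grouping \code{"cisplatin_vs_not"} or \code{"treatment"}.
#' @return Named numeric vector of mean prevalences.
#' @export
prevalence_by_cohort <- function(fractions, metadata,
                                 grouping = c("cisplatin_vs_not", "treatment")) {
  grouping <- match.arg(grouping)
  trt <- metadata$treatment[match(names(fractions), metadata$sample_id)]
  grp <- if (grouping == "cisplatin_vs_not") {
    ifelse(trt %in% c("cisplatin", "cisplatin_retreat"),
           "cisplatin", "non_cisplatin")
  } else trt
  ok <- !is.na(fractions) & !is.na(grp)
  if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
  means <- tapply(fractions[ok], grp[ok], mean)
  stats::setNames(as.numeric(means), names(means))
}
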