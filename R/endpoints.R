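# Subclone-genotype inference by endpoint extrapolation.
#
# Each marker is regressed on the anchor AF across samples; evaluating the
# fitted line at the anchor's two subclone AF values (default 0.25 and 0,
# the pure-subclone-1 and pure-subclone-2 anchor AFs) extrapolates the
# marker's value in each pure subclone. Those continuous endpoints are
# then resolved into integer genotypes.

#' Extrapolate per-marker subclone endpoints from an anchor marker
#'
#' For every marker other than the anchor, fits an OLS line of the marker
#' value on the anchor AF over complete cases
#' (\code{\link{fit_marker_pair}}) and evaluates it at the two anchor
#' values, giving the marker's estimated value in pure subclone 1 and
#' pure subclone 2. Markers whose fit fails (e.g. constant columns) are
#' reported in the \code{failures} attribute, not fatal.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param anchor marker id of the anchor AF assay (default
#'   \code{"LRP1B_AF"}).
#' @param anchor_values anchor AF of pure subclone 1 and pure subclone 2
#'   (default \code{c(0.25, 0)}).
#' @param ls_fit if \code{TRUE} (default) endpoints come from the OLS
#'   line; if \code{FALSE}, from the line through the two samples with
#'   extreme anchor AF (a two-point alternative to OLS).
#' @return A \code{data.frame} of class \code{"subclone_endpoints"} with
#'   columns \code{marker_id}, \code{gene}, \code{assay_kind},
#'   \code{value_subclone1}, \code{value_subclone2}, \code{slope},
#'   \code{intercept}, \code{r}, \code{p_value}, \code{n}; attribute
#'   \code{failures} is a named character vector of per-marker error
#'   messages and attribute \code{anchor}/\code{anchor_values} record the
#'   anchor used.
#' @export
infer_subclone_endpoints <- function(table, anchor = "LRP1B_AF",
                                     anchor_values = c(0.25, 0),
                                     ls_fit = TRUE) {
  stopifnot(inherits(table, "measurement_table"))
  if (!anchor %in% colnames(table$values)) {
    stop("anchor marker '", anchor, "' not in table")
  }
  if (table$panel$assay_kind[match(anchor, table$panel$marker_id)] != "AF") {
    stop("anchor must be an AF assay")
  }
  stopifnot(length(anchor_values) == 2L)
  x <- table$values[, anchor]
  out <- list(); failures <- character(0)
  for (mk in colnames(table$values)) {
    if (mk == anchor) {
      # the anchor's own endpoints are the anchor values by definition,
      # but evaluating its self-fit is a useful consistency check
      fit <- tryCatch(fit_marker_pair(x, x), error = function(e) NULL)
      out[[mk]] <- data.frame(
        marker_id = mk, value_subclone1 = anchor_values[1],
        value_subclone2 = anchor_values[2],
        slope = if (is.null(fit)) NA_real_ else fit$slope,
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        r = if (is.null(fit)) NA_real_ else fit$r,
        p_value = if (is.null(fit)) NA_real_ else fit$p_value,
        n = if (is.null(fit)) sum(is.finite(x)) else fit$n,
        stringsAsFactors = FALSE)
      next
    }
    y <- table$values[, mk]
    fit <- tryCatch(
      if (ls_fit) fit_marker_pair(x, y) else .two_point_fit(x, y),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      failures[mk] <- fit
      next
    }
    out[[mk]] <- data.frame(
      marker_id = mk,
      value_subclone1 = fit$intercept + fit$slope * anchor_values[1],
      value_subclone2 = fit$intercept + fit$slope * anchor_values[2],
      slope = fit$slope, intercept = fit$intercept, r = fit$r,
      p_value = fit$p_value, n = fit$n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- merge(table$panel, res, by = "marker_id", sort = FALSE)
  res <- res[match(intersect(colnames(table$values), res$marker_id),
                   res$marker_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("subclone_endpoints", "data.frame"),
            failures = failures, anchor = anchor,
            anchor_values = anchor_values)
}

# Line through the two samples at the extremes of the anchor AF.
.two_point_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs")
  xs <- x[ok]; ys <- y[ok]
  i <- which.min(xs); j <- which.max(xs)
  if (xs[i] == xs[j]) stop("x has zero variance; fit undefined")
  slope <- (ys[j] - ys[i]) / (xs[j] - xs[i])
  r <- tryCatch(stats::cor(xs, ys), error = function(e) NA_real_)
  list(slope = slope, intercept = ys[i] - slope * xs[i], r = r,
       p_value = NA_real_, n = sum(ok))
}

#' Resolve continuous subclone endpoints into integer genotypes
#'
#' Gene by gene, pairs the AF endpoint with the CN endpoint (averaging if
#' a gene has several CN assays) and calls
#' \code{\link{call_integer_genotype}} per subclone. Genes with only an AF
#' assay have no information about total copies and are genotyped under an
#' assumed diploid total (\code{t = 2}), flagged in the \code{assumed_t2}
#' column. Genes with only CN assays are recorded as \code{m = 0} with
#' \code{t = round(cn)}. AF endpoints extrapolated slightly outside
#' \[0, 1\] are clipped with a warning. The non-integer CN endpoint is
#' retained as the genotype's \code{mean_cn}.
#'
#' @param endpoints a \code{\link{infer_subclone_endpoints}} result.
#' @param panel a \code{\link{marker_panel}} (defaults to the panel
#'   columns carried in \code{endpoints}).
#' @return A list with \code{subclone1} and \code{subclone2}
#'   (\code{\link{subclone_genotype}} objects) and \code{calls}, a
#'   per-gene \code{data.frame} with the endpoints used, residuals, and
#'   the \code{assumed_t2} flag.
#' @export
genotype_subclones <- function(endpoints, panel = NULL) {
  stopifnot(inherits(endpoints, "subclone_endpoints") ||
              all(c("marker_id", "assay_kind", "gene",
                    "value_subclone1", "value_subclone2") %in% names(endpoints)))
  ep <- as.data.frame(endpoints)
  genes <- unique(ep$gene)
  rows <- list()
  for (g in genes) {
    sub <- ep[ep$gene == g, , drop = FALSE]
    af <- sub[sub$assay_kind == "AF", , drop = FALSE]
    cn <- sub[sub$assay_kind == "CN", , drop = FALSE]
    af1 <- if (nrow(af)) af$value_subclone1[1] else NA_real_
    af2 <- if (nrow(af)) af$value_subclone2[1] else NA_real_
    cn1 <- if (nrow(cn)) mean(cn$value_subclone1) else NA_real_
    cn2 <- if (nrow(cn)) mean(cn$value_subclone2) else NA_real_
    clip <- function(v) {
      if (!is.na(v) && (v < 0 || v > 1)) {
        warning(sprintf("AF endpoint %.3f for gene %s outside [0,1]; clipped",
                        v, g), call. = FALSE)
        v <- min(max(v, 0), 1)
      }
      v
    }
    af1 <- clip(af1); af2 <- clip(af2)
    assumed_t2 <- nrow(af) > 0 && nrow(cn) == 0
    call_one <- function(afv, cnv) {
      if (is.na(afv) && is.na(cnv)) return(list(m = NA, t = NA, residual = NA))
      if (is.na(afv)) {                       # CN-only gene: no mutation assay
        return(list(m = 0L, t = max(1L, as.integer(round(cnv))), residual = 0))
      }
      if (is.na(cnv)) cnv <- 2                # AF-only gene: assume diploid
      call_integer_genotype(afv, max(cnv, 0.51))
    }
    c1 <- call_one(af1, cn1); c2 <- call_one(af2, cn2)
    rows[[g]] <- data.frame(
      gene = g, af_endpoint1 = af1, af_endpoint2 = af2,
      cn_endpoint1 = cn1, cn_endpoint2 = cn2,
      m1 = c1$m, t1 = c1$t, residual1 = c1$residual,
      m2 = c2$m, t2 = c2$t, residual2 = c2$residual,
      assumed_t2 = assumed_t2, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  ok <- !is.na(calls$m1) & !is.na(calls$m2)
  g1 <- subclone_genotype(calls$gene[ok], calls$m1[ok], calls$t1[ok],
                          mean_cn = calls$cn_endpoint1[ok])
  g2 <- subclone_genotype(calls$gene[ok], calls$m2[ok], calls$t2[ok],
                          mean_cn = calls$cn_endpoint2[ok])
  list(subclone1 = g1, subclone2 = g2, calls = calls)
}

#' Per-sample mixing fractions from an anchor CN column
#'
#' Applies \code{\link{estimate_mixing_fraction}} to every sample's value
#' of the anchor CN marker (averaging multiple CN assays of the anchor
#' gene when present).
#'
#' @param table a \code{\link{measurement_table}}.
#' @param g1,g2 \code{\link{subclone_genotype}} objects.
#' @param anchor_gene gene whose CN assays anchor the interpolation
#'   (default \code{"LRP1B"}).
#' @param use endpoint basis passed to
#'   \code{\link{estimate_mixing_fraction}}.
#' @return Named numeric vector of mixing fractions (NA where the anchor
#'   CN is missing).
#' @export
estimate_fractions <- function(table, g1, g2, anchor_gene = "LRP1B",
                               use = c("total_copies", "mean_cn")) {
  stopifnot(inherits(table, "measurement_table"))
  use <- match.arg(use)
  cn_cols <- table$panel$marker_id[table$panel$gene == anchor_gene &
                                     table$panel$assay_kind == "CN"]
  if (!length(cn_cols)) stop("no CN assay for anchor gene '", anchor_gene, "'")
  cn <- rowMeans(table$values[, cn_cols, drop = FALSE], na.rm = TRUE)
  cn[is.nan(cn)] <- NA_real_
  p <- rep(NA_real_, length(cn))
  ok <- !is.na(cn)
  p[ok] <- estimate_mixing_fraction(cn[ok], g1, g2, anchor_gene, use = use)
  names(p) <- rownames(table$values)
  p
}
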