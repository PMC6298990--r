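# Two-subclone mixture model over paired AF/CN assays.
#
# Each sample is modeled as a mixture of two subclones with fixed integer
# genotypes; its mixing fraction p is the proportion of cells belonging to
# subclone 1. The observed CN at a locus is the cell-weighted mean copy
# number p*cn1 + (1-p)*cn2 (cn may be non-integer, representing residual
# within-subclone heterogeneity), and the observed AF is the template
# ratio (p*m1 + (1-p)*m2) / (p*T1 + (1-p)*T2): a ratio of affine
# functions of p, of which the straight lines used for inference are a
# close approximation over the observed mixing range.

#' Subclone genotype
#'
#' Describes one subclone as an integer genotype per locus: \code{m}
#' mutant copies out of \code{t} total copies (the locus AF implied is
#' \code{m/t}). An optional non-integer \code{mean_cn} records the mean
#' copy number at the CN-assay locus when the subclone is itself a mixture
#' of cells with different copy numbers; it defaults to \code{t}.
#'
#' @param locus character vector of locus (gene) names.
#' @param m integer vector of mutant copies, \code{0 <= m <= t}.
#' @param t integer vector of total copies, \code{t >= 1}.
#' @param mean_cn optional numeric vector of mean copy numbers (\code{NA}
#'   falls back to \code{t}).
#' @return A \code{data.frame} of class \code{"subclone_genotype"}.
#' @examples
#' subclone_genotype(c("LRP1B", "ERBB4"), m = c(1, 1), t = c(4, 3),
#'                   mean_cn = c(NA, 2.8))
#' @export
subclone_genotype <- function(locus, m, t, mean_cn = NULL) {
  locus <- as.character(locus)
  if (anyDuplicated(locus)) stop("duplicate locus in genotype")
  m <- as.integer(round(m)); t <- as.integer(round(t))
  if (any(t < 1L)) stop("total copies t must be >= 1")
  if (any(m < 0L) || any(m > t)) stop("mutant copies m must satisfy 0 <= m <= t")
  if (is.null(mean_cn)) mean_cn <- rep(NA_real_, length(locus))
  mean_cn <- as.numeric(mean_cn)
  if (any(!is.na(mean_cn) & mean_cn < 0)) stop("mean_cn must be >= 0")
  structure(
    data.frame(locus = locus, m = m, t = t,
               mean_cn = ifelse(is.na(mean_cn), as.numeric(t), mean_cn),
               stringsAsFactors = FALSE),
    class = c("subclone_genotype", "data.frame")
  )
}

.locus_row <- function(g, locus) {
  i <- match(locus, g$locus)
  if (is.na(i)) stop("locus '", locus, "' not in genotype")
  g[i, ]
}

#' Expected copy number of a subclone mixture
#'
#' The mean copy number of a sample that is a fraction \code{p} subclone 1
#' and \code{1 - p} subclone 2: \code{p * cn1 + (1 - p) * cn2}, affine and
#' strictly increasing in \code{p} when \code{cn1 > cn2}.
#'
#' @param p mixing fraction(s) in \[0, 1\] (proportion of subclone 1).
#' @param g1,g2 \code{\link{subclone_genotype}} objects.
#' @param locus locus name present in both genotypes.
#' @return Numeric vector of expected copy numbers.
#' @export
expected_copy_number <- function(p, g1, g2, locus) {
  stopifnot(all(p >= 0 & p <= 1))
  cn1 <- .locus_row(g1, locus)$mean_cn
  cn2 <- .locus_row(g2, locus)$mean_cn
  p * cn1 + (1 - p) * cn2
}

#' Expected allele frequency of a subclone mixture
#'
#' The mutant-template fraction of a mixed sample:
#' \deqn{AF(p) = (p m_1 + (1-p) m_2) / (p a_1 + (1-p) a_2)}
#' where \eqn{m_i} are mutant copies and \eqn{a_i} the allele totals of
#' the two subclones at the mutation locus. By default the integer totals
#' \code{t} are used (\code{denominator = "total_copies"}): the AF assay
#' interrogates the mutation site itself, whereas a non-integer
#' \code{mean_cn} describes heterogeneity seen by the CN assay. Setting
#' \code{denominator = "mean_cn"} mixes over \code{mean_cn} instead. The
#' result is a ratio of affine functions of \code{p} — slightly curved,
#' which is why line-based inference carries a small, documented
#' approximation error.
#'
#' @inheritParams expected_copy_number
#' @param denominator \code{"total_copies"} (default) or \code{"mean_cn"}.
#' @return Numeric vector of expected allele frequencies in \[0, 1\].
#' @export
expected_allele_frequency <- function(p, g1, g2, locus,
                                      denominator = c("total_copies", "mean_cn")) {
  stopifnot(all(p >= 0 & p <= 1))
  denominator <- match.arg(denominator)
  r1 <- .locus_row(g1, locus); r2 <- .locus_row(g2, locus)
  a1 <- if (denominator == "mean_cn") r1$mean_cn else r1$t
  a2 <- if (denominator == "mean_cn") r2$mean_cn else r2$t
  denom <- p * a1 + (1 - p) * a2
  if (any(denom <= 0)) stop("mixed copy number is zero at locus '", locus, "'")
  (p * r1$m + (1 - p) * r2$m) / denom
}

#' Call the integer genotype consistent with an (AF, CN) pair
#'
#' Total copies are fixed to \code{T = round(cn)} (minimum 1) and the
#' mutant copy count is the \code{m} in \code{0..T} minimizing
#' \code{|af - m/T|}, ties broken toward smaller \code{m}. The residual
#' \code{|af - m/T|} is returned as a consistency score: for a homogeneous
#' cell population it should be within measurement noise of zero.
#'
#' @param af allele frequency in \[0, 1\].
#' @param cn copy number, must exceed 0.5 so that at least one copy is
#'   present.
#' @return A list with elements \code{m}, \code{t}, \code{residual}.
#' @examples
#' call_integer_genotype(0.33, 2.9)  # 1 mutant of 3 copies
#' @export
call_integer_genotype <- function(af, cn) {
  if (is.na(af) || is.na(cn)) stop("af and cn must be non-missing")
  if (af < 0 || af > 1) stop("af must be in [0,1], got ", af)
  if (cn <= 0.5) stop("cn must exceed 0.5, got ", cn)
  t <- max(1L, as.integer(round(cn)))
  m_grid <- 0:t
  resid <- abs(af - m_grid / t)
  m <- m_grid[which.min(resid)]          # which.min takes the smaller m on ties
  list(m = as.integer(m), t = t, residual = min(resid))
}

#' Ordinary least-squares line fit with Pearson correlation
#'
#' Fits \code{y ~ x} by OLS over complete pairs and reports the Pearson
#' correlation with its two-sided p-value from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; pairs with any \code{NA}
#'   are dropped; at least 3 complete pairs are required.
#' @return A list of class \code{"line_fit"}: \code{slope},
#'   \code{intercept}, \code{r}, \code{p_value}, \code{n}.
#' @export
fit_marker_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs, got ", n)
  if (stats::sd(x) == 0) stop("x has zero variance; fit undefined")
  if (stats::sd(y) == 0) stop("y has zero variance; correlation undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(slope = slope, intercept = intercept, r = r,
                 p_value = p, n = n),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("line_fit: y = %.4g + %.4g x   (r = %.3f, p = %.3g, n = %d)\n",
              x$intercept, x$slope, x$r, x$p_value, x$n))
  invisible(x)
}

#' Estimate the mixing fraction of a sample from an anchor copy number
#'
#' Linear interpolation of the observed anchor CN between the two
#' subclones' copy numbers: \code{p = (cn - cn2) / (cn1 - cn2)}, clipped
#' to \[0, 1\]. By default the integer total copies of the genotypes are
#' used as interpolation endpoints (e.g. 4 and 2 for an anchor with
#' genotypes 1-of-4 and 0-of-2); \code{use = "mean_cn"} interpolates
#' between the fitted non-integer endpoints instead.
#'
#' @param cn observed anchor copy number(s).
#' @param g1,g2 \code{\link{subclone_genotype}} objects.
#' @param anchor locus name of the anchor marker.
#' @param use \code{"total_copies"} (default) or \code{"mean_cn"}.
#' @return Mixing fraction(s) in \[0, 1\] (NA propagated).
#' @export
estimate_mixing_fraction <- function(cn, g1, g2, anchor,
                                     use = c("total_copies", "mean_cn")) {
  use <- match.arg(use)
  r1 <- .locus_row(g1, anchor); r2 <- .locus_row(g2, anchor)
  cn1 <- if (use == "mean_cn") r1$mean_cn else r1$t
  cn2 <- if (use == "mean_cn") r2$mean_cn else r2$t
  if (cn1 == cn2) stop("anchor '", anchor,
                       "' has equal copy number in both subclones; uninformative")
  pmin(pmax((cn - cn2) / (cn1 - cn2), 0), 1)
}

#' Propagate AF measurement uncertainty to subclone cellularity
#'
#' For a heterozygous mutation private to one subclone on a diploid
#' background, the cellularity of the mutant subclone is \code{2 * AF};
#' an AF standard deviation therefore maps to a cellularity standard
#' deviation of \code{2 * af_sd}.
#'
#' @param af_sd AF standard deviation(s), >= 0.
#' @return Cellularity standard deviation(s), as a fraction of cells.
#' @examples
#' cellularity_uncertainty(0.011)  # 0.022, i.e. 2.2% of cells
#' @export
cellularity_uncertainty <- function(af_sd) {
  stopifnot(all(af_sd >= 0))
  2 * af_sd
}

#' Distance of a copy-number value from the nearest integer
#'
#' \code{|cn - round(cn)|}, in \[0, 0.5\]. A subclone-level mean copy
#' number far from an integer implies the subclone is internally
#' heterogeneous (each individual cell carries an integer number of
#' copies), so this deviation is a per-subclone heterogeneity signal.
#'
#' @param cn copy number(s), >= 0.
#' @return Deviation(s) in \[0, 0.5\].
#' @export
integer_deviation <- function(cn) {
  stopifnot(all(cn >= 0))
  abs(cn - round(cn))
}
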