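# Bottleneck-outlier detection.
#
# Two branches, matching the structure of the data:
#  - loci not affected by two-subclone mixing (stable AF across samples)
#    are screened by a median-centered z-score, |z| > 3;
#  - loci whose AF varies with the mixing fraction are screened by the
#    perpendicular Euclidean distance D of the (anchor AF, marker AF)
#    point to the declared mixing line, D > 0.07 — far beyond the 0.011
#    ddPCR AF measurement uncertainty, deliberately stringent because the
#    precursor mixture of an outlier sample is unknown.
# Samples violating either rule carry a cell population not explainable
# by mixing of the two recurrent subclones, i.e. a population bottleneck.

#' Mixing line between two subclone endpoints
#'
#' A line in the (x, y) AF plane joining the pure-subclone-2 and
#' pure-subclone-1 expectations of a marker pair, against which samples
#' are tested for bottleneck outliers.
#'
#' @param x_marker,y_marker marker ids of the predictor (anchor) and
#'   response AF assays.
#' @param endpoint_a,endpoint_b numeric \code{(x, y)} pairs; must be
#'   distinct and must differ in x.
#' @return A list of class \code{"mixing_line"}.
#' @export
mixing_line <- function(x_marker, y_marker, endpoint_a, endpoint_b) {
  stopifnot(length(endpoint_a) == 2L, length(endpoint_b) == 2L)
  if (all(endpoint_a == endpoint_b)) stop("mixing line endpoints must differ")
  if (endpoint_a[1] == endpoint_b[1]) {
    stop("mixing line is vertical in x; cannot classify excess/deficient y")
  }
  structure(list(x_marker = x_marker, y_marker = y_marker,
                 endpoint_a = as.numeric(endpoint_a),
                 endpoint_b = as.numeric(endpoint_b)),
            class = "mixing_line")
}

#' Default mixing lines
#'
#' The three marker-vs-anchor lines used for D-based outlier calls, with
#' LRP1B AF as predictor: ERBB4 (0,0)--(0.25,0.33), MET
#' (0,0.67)--(0.25,0.5), SAAL1 (0,0.25)--(0.25,0.4).
#'
#' @return A list of \code{\link{mixing_line}} objects.
#' @export
default_mixing_lines <- function() {
  list(
    mixing_line("LRP1B_AF", "ERBB4_AF", c(0, 0), c(0.25, 0.33)),
    mixing_line("LRP1B_AF", "MET_AF", c(0, 0.67), c(0.25, 0.5)),
    mixing_line("LRP1B_AF", "SAAL1_AF", c(0, 0.25), c(0.25, 0.4))
  )
}

#' Median-centered z-scores
#'
#' \code{z_i = (v_i - median(v)) / sd(v)} with the sample (n-1) standard
#' deviation taken over all non-missing values, candidate outliers
#' included (which slightly masks extreme values; documented caveat). A
#' zero standard deviation yields all-zero z (no outliers by convention).
#'
#' @param values numeric vector with at least 3 non-missing entries.
#' @return Numeric vector of z-scores, \code{NA} preserved in place.
#' @export
median_z_scores <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need >= 3 non-missing values, got ", sum(ok))
  s <- stats::sd(values[ok])
  med <- stats::median(values[ok])
  z <- rep(NA_real_, length(values))
  z[ok] <- if (s == 0) 0 else (values[ok] - med) / s
  z
}

#' Signed perpendicular distance of a point to a mixing line
#'
#' Standard Euclidean distance from the point to the infinite line through
#' the two endpoints. The sign classifies direction: positive when the
#' point lies above the line in y at its x value (excess), negative below
#' (deficient). Invariant under swapping the endpoints.
#'
#' @param point numeric \code{(x, y)} pair, or a two-column matrix of
#'   points.
#' @param line a \code{\link{mixing_line}}.
#' @return A list with \code{distance} (>= 0) and \code{signed} (same
#'   magnitude, sign of the y-residual); vectors if \code{point} is a
#'   matrix.
#' @export
perpendicular_distance <- function(point, line) {
  stopifnot(inherits(line, "mixing_line"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  a <- line$endpoint_a; b <- line$endpoint_b
  slope <- (b[2] - a[2]) / (b[1] - a[1])
  intercept <- a[2] - slope * a[1]
  resid <- pts[, 2] - (intercept + slope * pts[, 1])
  signed <- resid / sqrt(1 + slope^2)
  list(distance = abs(signed), signed = signed)
}

#' Classify bottleneck outliers across a panel
#'
#' Applies the median-z rule (\code{|z| > z_threshold}, strict) to each
#' stable marker and the perpendicular-distance rule
#' (\code{D > d_threshold}, strict) to each mixing line, building a
#' sample-by-dimension call matrix: \code{+1} excess, \code{-1}
#' deficient, \code{0} not flagged, \code{NA} not evaluable (missing
#' measurement). Direction for stable markers is the sign of z; for
#' mixing dimensions it is the sign of the y-residual at the sample's x.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param stable_markers marker ids screened by z-score; defaults to the
#'   AF assays of BRCA2, PTCH1, TP53 and CSMD3, intersected with the
#'   markers present in the table.
#' @param mixing_lines list of \code{\link{mixing_line}} objects
#'   (default \code{\link{default_mixing_lines}()}), restricted to lines
#'   whose markers are present.
#' @param z_threshold,d_threshold flag thresholds (defaults 3 and 0.07,
#'   both strict inequalities).
#' @return A list of class \code{"outlier_calls"}: \code{calls} (integer
#'   matrix samples x dimensions), \code{z} and \code{d} (the underlying
#'   statistics), \code{n_flagged}, \code{dimensions_per_sample},
#'   \code{max_dimensions}, \code{n_patterns} (distinct multisets of
#'   flagged dimension+sign over flagged samples), and
#'   \code{flagged_by_source} when sample metadata carry a \code{source}
#'   column.
#' @export
classify_outliers <- function(table,
                              stable_markers = c("BRCA2_AF", "PTCH1_AF",
                                                 "TP53_AF", "CSMD3_AF"),
                              mixing_lines = default_mixing_lines(),
                              z_threshold = 3, d_threshold = 0.07) {
  stopifnot(inherits(table, "measurement_table"))
  vals <- table$values
  stable_markers <- intersect(stable_markers, colnames(vals))
  mixing_lines <- Filter(function(l) {
    l$x_marker %in% colnames(vals) && l$y_marker %in% colnames(vals)
  }, mixing_lines)
  dims <- c(stable_markers, vapply(mixing_lines, `[[`, "", "y_marker"))
  if (!length(dims)) stop("no evaluable outlier dimensions in table")
  ns <- nrow(vals)
  calls <- matrix(NA_integer_, ns, length(dims),
                  dimnames = list(rownames(vals), dims))
  zmat <- matrix(NA_real_, ns, length(stable_markers),
                 dimnames = list(rownames(vals), stable_markers))
  dmat <- matrix(NA_real_, ns, length(mixing_lines),
                 dimnames = list(rownames(vals),
                                 vapply(mixing_lines, `[[`, "", "y_marker")))
  for (mk in stable_markers) {
    z <- median_z_scores(vals[, mk])
    zmat[, mk] <- z
    flag <- !is.na(z) & abs(z) > z_threshold
    calls[, mk] <- ifelse(is.na(z), NA_integer_,
                          ifelse(flag, ifelse(z > 0, 1L, -1L), 0L))
  }
  for (l in mixing_lines) {
    pts <- cbind(vals[, l$x_marker], vals[, l$y_marker])
    pd <- perpendicular_distance(pts, l)
    dmat[, l$y_marker] <- pd$distance
    ok <- !is.na(pd$distance)
    flag <- ok & pd$distance > d_threshold
    calls[, l$y_marker] <- ifelse(!ok, NA_integer_,
                                  ifelse(flag, ifelse(pd$signed > 0, 1L, -1L),
                                         0L))
  }
  flagged <- as.integer(rowSums(calls != 0L, na.rm = TRUE))
  names(flagged) <- rownames(vals)
  patt <- vapply(seq_len(ns), function(i) {
    hit <- which(!is.na(calls[i, ]) & calls[i, ] != 0L)
    if (!length(hit)) return("")
    paste(sort(paste0(dims[hit], ifelse(calls[i, hit] > 0, "+", "-"))),
          collapse = ",")
  }, "")
  is_out <- flagged > 0
  res <- list(
    calls = calls, z = zmat, d = dmat,
    dimensions_per_sample = flagged,
    n_flagged = sum(is_out),
    max_dimensions = if (any(is_out)) max(flagged) else 0L,
    n_patterns = length(unique(patt[is_out])),
    patterns = patt,
    z_threshold = z_threshold, d_threshold = d_threshold
  )
  if (!is.null(table$samples) && "source" %in% names(table$samples)) {
    src <- ifelse(table$samples$source %in% c("crpc_bulk", "crpc_clone"),
                  "crpc", "xenograft")
    res$flagged_by_source <- tapply(is_out, src, mean)
  }
  structure(res, class = "outlier_calls")
}

#' @export
print.outlier_calls <- function(x, ...) {
  cat(sprintf(
    "outlier_calls: %d of %d samples flagged (max %d dimensions, %d distinct patterns)\n",
    x$n_flagged, nrow(x$calls), x$max_dimensions, x$n_patterns))
  if (!is.null(x$flagged_by_source)) {
    cat("flagged fraction by source:",
        paste(sprintf("%s=%.2f", names(x$flagged_by_source),
                      x$flagged_by_source), collapse = " "), "\n")
  }
  invisible(x)
}
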