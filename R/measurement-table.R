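# Central data container: a samples x markers matrix of ddPCR summary
# values (AF assays in [0,1], CN assays >= 0, NA allowed), tied to a
# marker panel and optionally to per-sample metadata.

.treatment_levels <- c("none", "vehicle", "cisplatin", "cisplatin_retreat",
                       "docetaxel", "doxorubicin", "cyclophosphamide")
.source_levels <- c("xenograft", "crpc_bulk", "crpc_clone")

#' Construct a measurement table
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids). \code{NA} marks a
#'   measurement that was not obtained.
#' @param panel a \code{\link{marker_panel}} covering every column.
#' @param samples optional per-sample metadata \code{data.frame} as
#'   returned by \code{\link{read_sample_metadata}}; must contain a
#'   \code{sample_id} column matching the rownames of \code{values}.
#' @return An object of class \code{"measurement_table"}: a list with
#'   elements \code{values}, \code{panel}, \code{samples}.
#' @export
measurement_table <- function(values, panel, samples = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must have sample ids as rownames")
  if (is.null(colnames(values))) stop("values must have marker ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate sample_id in values")
  unknown <- setdiff(colnames(values), panel$marker_id)
  if (length(unknown)) {
    stop("columns not declared in panel: ", paste(unknown, collapse = ", "))
  }
  panel <- panel[match(colnames(values), panel$marker_id), , drop = FALSE]
  .validate_ranges(values, panel)
  if (!is.null(samples)) {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(samples)) stop("samples must have sample_id")
    miss <- setdiff(rownames(values), samples$sample_id)
    if (length(miss)) {
      stop("metadata missing for samples: ", paste(miss, collapse = ", "))
    }
    samples <- samples[match(rownames(values), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(values = values, panel = panel, samples = samples),
            class = "measurement_table")
}

.validate_ranges <- function(values, panel) {
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    kind <- panel$assay_kind[j]
    bad <- if (kind == "AF") which(!is.na(v) & (v < 0 | v > 1)) else
      which(!is.na(v) & v < 0)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "%s value %.4g out of range for marker '%s' in sample '%s'%s",
        kind, v[i], colnames(values)[j], rownames(values)[i],
        if (kind == "AF") " (AF must be a fraction in [0,1], not a percent)"
        else " (CN must be >= 0)"))
    }
  }
  invisible(TRUE)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("measurement_table: %d samples x %d markers (%d AF, %d CN), %d missing cells\n",
              nrow(x$values), ncol(x$values),
              sum(x$panel$assay_kind == "AF"),
              sum(x$panel$assay_kind == "CN"),
              sum(is.na(x$values))))
  if (!is.null(x$samples) && "treatment" %in% names(x$samples)) {
    tab <- table(x$samples$treatment)
    cat("treatments:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.measurement_table <- function(x) dim(x$values)

#' Read a ddPCR measurement table from CSV
#'
#' The file is comma-separated UTF-8 with a header row; the first column is
#' \code{sample_id} and every remaining column is a declared
#' \code{marker_id}. \code{"NA"} and the empty string both mean missing.
#' AF values must already be fractions in \[0, 1\]; percentages are
#' rejected rather than silently rescaled.
#'
#' @param path path to the CSV file.
#' @param panel a \code{\link{marker_panel}} declaring every marker column.
#' @param metadata optional metadata \code{data.frame} to attach (see
#'   \code{\link{read_sample_metadata}}).
#' @return A \code{\link{measurement_table}}.
#' @export
read_measurements <- function(path, panel, metadata = NULL) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("measurement table needs sample_id plus >= 1 marker")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  nonnum <- which(colSums(is.na(vals)) > colSums(is.na(df[, -1L, drop = FALSE])))
  if (length(nonnum)) {
    stop("non-numeric entries in marker column(s): ",
         paste(colnames(vals)[nonnum], collapse = ", "))
  }
  rownames(vals) <- ids
  measurement_table(vals, panel, samples = metadata)
}

#' Write a measurement table to CSV
#'
#' Inverse of \code{\link{read_measurements}}: missing cells are written as
#' empty fields and full double precision is kept, so a read/write round
#' trip reproduces values exactly.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    df[[colnames(vals)[j]]] <- sprintf("%.17g", vals[, j])
    df[[colnames(vals)[j]]][is.na(vals[, j])] <- ""
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-sample metadata from CSV
#'
#' Required column: \code{sample_id} (unique). Optional columns:
#' \code{model_id}, \code{source} (one of xenograft, crpc_bulk,
#' crpc_clone), \code{treatment} (one of none, vehicle, cisplatin,
#' cisplatin_retreat, docetaxel, doxorubicin, cyclophosphamide),
#' \code{volume_change_pct} (percent change of tumor volume, >= -100,
#' missing allowed), \code{days}, \code{spatial_label}.
#'
#' @param path path to the CSV file.
#' @return A \code{data.frame} with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("metadata must have sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if ("treatment" %in% names(df)) {
    bad <- !is.na(df$treatment) & !df$treatment %in% .treatment_levels
    if (any(bad)) {
      stop("unknown treatment label(s): ",
           paste(unique(df$treatment[bad]), collapse = ", "),
           " (allowed: ", paste(.treatment_levels, collapse = ", "), ")")
    }
  }
  if ("source" %in% names(df)) {
    bad <- !is.na(df$source) & !df$source %in% .source_levels
    if (any(bad)) {
      stop("unknown source label(s): ",
           paste(unique(df$source[bad]), collapse = ", "))
    }
  }
  if ("volume_change_pct" %in% names(df)) {
    df$volume_change_pct <- as.numeric(df$volume_change_pct)
    bad <- !is.na(df$volume_change_pct) & df$volume_change_pct < -100
    if (any(bad)) stop("volume_change_pct below -100% in sample ",
                       df$sample_id[which(bad)[1L]])
  }
  if ("days" %in% names(df)) df$days <- as.numeric(df$days)
  df
}

#' Write sample metadata to CSV
#' @param metadata a metadata \code{data.frame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a table to samples complete for a set of markers
#'
#' Keeps, in their original order, only the samples with no missing value
#' among the requested markers (for analyses that need the same sample set
#' for all variables, e.g. complete-case correlation matrices).
#'
#' @param table a \code{\link{measurement_table}}.
#' @param markers character vector of marker ids (default: all markers).
#' @return A \code{\link{measurement_table}} with the surviving samples.
#' @export
complete_case_subset <- function(table, markers = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  if (is.null(markers)) markers <- colnames(table$values)
  missing_m <- setdiff(markers, colnames(table$values))
  if (length(missing_m)) {
    stop("markers not in table: ", paste(missing_m, collapse = ", "))
  }
  keep <- rowSums(is.na(table$values[, markers, drop = FALSE])) == 0L
  if (!any(keep)) warning("no sample is complete for the requested markers")
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  if (!is.null(table$samples)) {
    out$samples <- table$samples[keep, , drop = FALSE]
    rownames(out$samples) <- NULL
  }
  out
}
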