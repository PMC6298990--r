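#' Marker panel definitions
#'
#' A marker panel declares, for every assay in a ddPCR study, the gene it
#' targets and whether it reports an allele frequency (\code{"AF"}, a
#' fraction of mutant templates in \[0, 1\]) or an absolute copy number
#' (\code{"CN"}, mean copies per cell, >= 0). A gene may carry both an AF
#' and a CN assay, and several CN assays at different loci; the
#' \code{marker_id} is therefore the unit of identity, not the gene.
#'
#' @param marker_id character vector of unique assay identifiers
#'   (conventionally \code{"<GENE>_AF"}, \code{"<GENE>_CN"}).
#' @param gene character vector of gene symbols, recycled if length 1.
#' @param assay_kind character vector of \code{"AF"} or \code{"CN"}.
#' @return A \code{data.frame} of class \code{"marker_panel"} with columns
#'   \code{marker_id}, \code{gene}, \code{assay_kind}.
#' @examples
#' marker_panel(c("LRP1B_AF", "LRP1B_CN"), "LRP1B", c("AF", "CN"))
#' @export
marker_panel <- function(marker_id, gene, assay_kind) {
  marker_id <- as.character(marker_id)
  gene <- rep_len(as.character(gene), length(marker_id))
  assay_kind <- rep_len(as.character(assay_kind), length(marker_id))
  if (anyDuplicated(marker_id)) {
    stop("duplicate marker_id in panel: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  }
  bad <- !assay_kind %in% c("AF", "CN")
  if (any(bad)) {
    stop("assay_kind must be 'AF' or 'CN' (marker ",
         paste(marker_id[bad], collapse = ", "), ")")
  }
  structure(
    data.frame(marker_id = marker_id, gene = gene, assay_kind = assay_kind,
               stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame")
  )
}

#' Read a marker panel from a YAML or CSV config file
#'
#' The panel file declares \code{marker_id}, \code{gene} and
#' \code{assay_kind} for every assay, rather than inferring the assay kind
#' from column names (which cannot be done reliably). YAML files hold a
#' list of records under top-level key \code{markers} (or a bare list);
#' CSV files hold the three columns directly.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.csv} file.
#' @return A \code{\link{marker_panel}}.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$markers)) cfg <- cfg$markers
    if (length(cfg) == 0L) stop("panel config is empty: ", path)
    marker_panel(
      marker_id = vapply(cfg, function(m) as.character(m$marker_id), ""),
      gene = vapply(cfg, function(m) as.character(m$gene), ""),
      assay_kind = vapply(cfg, function(m) as.character(m$assay_kind), "")
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("marker_id", "gene", "assay_kind")
    if (!all(need %in% names(df))) {
      stop("panel CSV must have columns: ", paste(need, collapse = ", "))
    }
    marker_panel(df$marker_id, df$gene, df$assay_kind)
  }
}

#' Write a marker panel to a YAML config file
#'
#' @param panel a \code{\link{marker_panel}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  recs <- lapply(seq_len(nrow(panel)), function(i) {
    list(marker_id = panel$marker_id[i], gene = panel$gene[i],
         assay_kind = panel$assay_kind[i])
  })
  yaml::write_yaml(list(markers = recs), path)
  invisible(path)
}

#' Default demonstration marker panel
#'
#' The assay panel the synthetic-data generator emulates: seven AF assays
#' (BRCA2, PTCH1, TP53, SAAL1, ERBB4, LRP1B, MET) and nine CN assays (two
#' LRP1B loci, ERBB4, EPHA3, EPHA5, PTPRD, AR, and the diploid control
#' loci EXOC4 and AKR1B1).
#'
#' @return A \code{\link{marker_panel}} with 16 markers.
#' @export
default_panel <- function() {
  marker_panel(
    marker_id = c("BRCA2_AF", "PTCH1_AF", "TP53_AF", "SAAL1_AF",
                  "ERBB4_AF", "LRP1B_AF", "MET_AF",
                  "LRP1B_CN", "LRP1B_CN2", "ERBB4_CN", "EPHA3_CN",
                  "EPHA5_CN", "PTPRD_CN", "AR_CN", "EXOC4_CN", "AKR1B1_CN"),
    gene = c("BRCA2", "PTCH1", "TP53", "SAAL1", "ERBB4", "LRP1B", "MET",
             "LRP1B", "LRP1B", "ERBB4", "EPHA3", "EPHA5", "PTPRD", "AR",
             "EXOC4", "AKR1B1"),
    assay_kind = c(rep("AF", 7), rep("CN", 9))
  )
}
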