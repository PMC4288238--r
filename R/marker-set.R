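#' Construct a marker set
#'
#' A marker set maps each cell type to the probesets (with gene symbols)
#' whose expression is essentially restricted to that cell type; these seed
#' the per-cell-type reference expression signals. A probeset may appear
#' under at most one cell type.
#'
#' @param markers Named list, one element per cell type, each a named
#'   character vector `probeset_id = gene_symbol` (or an unnamed character
#'   vector of probeset IDs, in which case gene symbols default to the
#'   probeset IDs).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(markers) {
  if (!is.list(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers))))
    stop("`markers` must be a named list keyed by cell type")
  markers <- lapply(markers, function(x) {
    x <- unlist(x)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      x <- stats::setNames(as.character(x), as.character(x))
    else
      x <- stats::setNames(as.character(x), names(x))
    # stored as probeset_id -> gene_symbol
    x
  })
  all_ps <- unlist(lapply(markers, names), use.names = FALSE)
  if (anyDuplicated(all_ps)) {
    dup <- unique(all_ps[duplicated(all_ps)])
    stop("probeset(s) listed under more than one cell type: ",
         paste(dup, collapse = ", "))
  }
  structure(markers, class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set with", length(x), "cell types:\n")
  for (ct in names(x))
    cat(sprintf("  %-16s %2d probesets (%s)\n", ct, length(x[[ct]]),
                paste(unique(unname(x[[ct]])), collapse = ", ")))
  invisible(x)
}

marker_probesets <- function(markers) {
  unlist(lapply(unclass(markers), names), use.names = FALSE)
}

#' Load a marker set from file
#'
#' Reads a marker set from either YAML (mapping cell type to a list of
#' `probeset_id: gene_symbol` entries or plain probeset IDs) or TSV (columns
#' `cell_type`, `probeset_id`, `gene_symbol`). Curated marker lists for the
#' brain datasets the method was developed on are bundled under
#' `system.file("extdata", package = "pseamix")`:
#' `markers_hd_ba4.tsv` (motor cortex), `markers_pd_cortex.tsv` (prefrontal
#' cortex) and `markers_pd_nigra_putamen.tsv` (substantia nigra / putamen).
#'
#' @param path Path to a `.yaml`/`.yml` or `.tsv` marker file.
#' @return A [marker_set()].
#' @export
load_marker_set <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    markers <- lapply(raw, function(entries) {
      if (is.list(entries)) {
        ps <- vapply(entries, function(e)
          if (is.list(e) || !is.null(names(e))) names(e)[1] else
            as.character(e)[1], character(1))
        gs <- vapply(entries, function(e)
          if (!is.null(names(e))) as.character(e[[1]]) else
            as.character(e)[1], character(1))
        stats::setNames(gs, ps)
      } else {
        stats::setNames(as.character(entries), as.character(entries))
      }
    })
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("cell_type", "probeset_id", "gene_symbol")
    if (!all(need %in% names(df)))
      stop("marker TSV must have columns ", paste(need, collapse = ", "))
    markers <- lapply(split(df, factor(df$cell_type,
                                       levels = unique(df$cell_type))),
                      function(d) stats::setNames(d$gene_symbol,
                                                  d$probeset_id))
  }
  marker_set(markers)
}

#' Check a marker set against a dataset
#'
#' Verifies that every marker probeset exists in the dataset.
#'
#' @param markers A [marker_set()].
#' @param dataset An [expression_dataset()].
#' @return Invisibly `TRUE`; errors listing missing probesets otherwise.
#' @export
check_markers <- function(markers, dataset) {
  missing <- setdiff(marker_probesets(markers), rownames(dataset$matrix))
  if (length(missing))
    stop("marker probesets absent from dataset: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
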