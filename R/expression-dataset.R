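#' Construct an expression dataset
#'
#' Bundles a probeset-by-sample expression matrix (linear scale, arbitrary
#' normalized units) with per-sample group labels and an optional
#' probeset-to-gene annotation map. This is the container every downstream
#' stage of the deconvolution pipeline operates on.
#'
#' @param matrix Numeric matrix, probesets in rows, samples in columns. Row
#'   and column names are required and must be unique. Values must be finite
#'   and non-negative (linear scale).
#' @param groups Character or factor of length `ncol(matrix)` with values in
#'   `c("control", "disease")`, optionally named by sample ID.
#' @param gene_map Optional named character vector mapping probeset IDs to
#'   gene symbols (HGNC-style). Probesets without an entry are retained and
#'   reported by probeset ID.
#' @param log_detected Logical flag recording whether the matrix was
#'   detected as log2-encoded on import and exponentiated.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `groups` (factor, levels control/disease, named by sample),
#'   `gene_map` and `log_detected`.
#' @seealso [read_expression()], [write_expression()]
#' @export
expression_dataset <- function(matrix, groups, gene_map = NULL,
                               log_detected = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have probeset row names and sample column names")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated probeset IDs: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]),
               collapse = ", "))
  if (any(!is.finite(matrix)))
    stop("expression matrix contains non-finite values")
  if (any(matrix < 0))
    stop("expression matrix contains negative values; expected linear-scale ",
         "intensities")
  if (length(groups) != ncol(matrix))
    stop("`groups` must have one label per sample")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(matrix), names(groups))
    if (length(missing))
      stop("samples missing from `groups`: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(matrix)]
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("control", "disease"))
  if (length(bad))
    stop("group labels must be 'control' or 'disease'; found: ",
         paste(bad, collapse = ", "))
  groups <- factor(groups, levels = c("control", "disease"))
  names(groups) <- colnames(matrix)
  if (!is.null(gene_map)) {
    if (is.null(names(gene_map)))
      stop("`gene_map` must be named by probeset ID")
    gene_map <- gene_map[!is.na(gene_map) & nzchar(gene_map)]
  }
  structure(
    list(matrix = matrix, groups = groups, gene_map = gene_map,
         log_detected = isTRUE(log_detected)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$matrix), "probesets x",
      ncol(x$matrix), "samples\n")
  cat("  groups:", sum(x$groups == "control"), "control,",
      sum(x$groups == "disease"), "disease\n")
  cat("  annotated probesets:", length(x$gene_map), "\n")
  if (x$log_detected)
    cat("  (input detected as log2 scale and exponentiated)\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

# Gene symbol for each probeset id; NA where unannotated.
gene_of <- function(dataset, probeset_ids) {
  if (is.null(dataset$gene_map)) return(rep(NA_character_,
                                            length(probeset_ids)))
  out <- unname(dataset$gene_map[probeset_ids])
  out[!nzchar(out)] <- NA_character_
  out
}

#' Read an expression dataset from TSV files
#'
#' Reads a probeset-by-sample expression matrix (first column probeset IDs,
#' header row of sample IDs), a sample metadata table with columns
#' `sample_id` and `group`, and optionally a probeset annotation table with
#' columns `probeset_id` and `hgnc_symbol`.
#'
#' Microarray intensities on a linear scale far exceed 30, whereas
#' log2-transformed values do not: if the maximum value of the matrix is
#' below 30 the matrix is treated as log2-encoded, exponentiated base 2, and
#' the `log_detected` flag is set. Deconvolution is linear in cell
#' abundance, so all modeling is done on the linear scale.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV (`sample_id`,
#'   `group`).
#' @param annotation_path Optional path to an annotation TSV
#'   (`probeset_id`, `hgnc_symbol`).
#' @param log_threshold Maximum-value threshold below which the matrix is
#'   treated as log2-encoded (default 30).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            annotation_path = NULL, log_threshold = 30) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (anyDuplicated(mat_df[[1]]))
    stop("duplicated probeset IDs in ", matrix_path)
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric expression values in ", matrix_path)
  rownames(mat) <- as.character(mat_df[[1]])

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must have columns sample_id and group")
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  missing_mat <- setdiff(meta$sample_id, colnames(mat))
  if (length(missing_meta) || length(missing_mat))
    stop("sample IDs inconsistent between matrix and metadata; ",
         if (length(missing_meta))
           paste0("missing from metadata: ",
                  paste(missing_meta, collapse = ", "), "; "),
         if (length(missing_mat))
           paste0("missing from matrix: ",
                  paste(missing_mat, collapse = ", ")))
  groups <- stats::setNames(meta$group, meta$sample_id)

  log_detected <- max(mat) < log_threshold
  if (log_detected) mat <- 2^mat

  gene_map <- NULL
  if (!is.null(annotation_path)) gene_map <- read_annotation(annotation_path)

  expression_dataset(mat, groups, gene_map, log_detected = log_detected)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: writes the matrix (probeset IDs in the
#' first column) and the sample metadata table. The round trip is lossless
#' for IDs, groups and values to printed precision.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(probeset_id = rownames(dataset$matrix),
                   dataset$matrix, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(dataset$groups),
                     group = as.character(dataset$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Read a probeset-to-gene annotation table
#'
#' @param path TSV with columns `probeset_id` and `hgnc_symbol`.
#' @return Named character vector, probeset ID to gene symbol.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probeset_id", "hgnc_symbol") %in% names(ann)))
    stop("annotation must have columns probeset_id and hgnc_symbol")
  stats::setNames(as.character(ann$hgnc_symbol), ann$probeset_id)
}

#' Read an ortholog map
#'
#' Static two-column table mapping foreign (e.g. mouse) probeset or gene
#' identifiers to HGNC gene symbols; used when validating cell-type
#' assignments against external cell-type-resolved expression tables.
#'
#' @param path TSV with columns `foreign_id` and `hgnc_symbol`.
#' @return Named character vector, foreign ID to gene symbol.
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("foreign_id", "hgnc_symbol") %in% names(map)))
    stop("ortholog map must have columns foreign_id and hgnc_symbol")
  stats::setNames(as.character(map$hgnc_symbol), map$foreign_id)
}
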