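#' Construct a cell-type expression table
#'
#' External cell-type-resolved expression (e.g. sorted-culture or TRAP
#' profiles) used to corroborate cell-type assignments: a gene-by-cell-type
#' matrix of normalized expression units after ortholog mapping.
#'
#' @param matrix Numeric matrix, unique gene symbols in rows, cell types
#'   in columns, non-negative values.
#' @param source_label Short label for the data source.
#' @return The matrix with class `celltype_expression_table` and attribute
#'   `source`.
#' @export
celltype_expression_table <- function(matrix, source_label = "external") {
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("gene symbols must be unique row names")
  if (any(matrix < 0, na.rm = TRUE)) stop("expression must be non-negative")
  structure(matrix, class = c("celltype_expression_table", class(matrix)),
            source = source_label)
}

#' Map foreign identifiers of an expression table to gene symbols
#'
#' Replaces foreign (e.g. mouse probeset) row identifiers with HGNC gene
#' symbols via a static ortholog map. Rows whose identifier is not in the
#' map are dropped (count logged); several foreign rows mapping to one
#' gene are collapsed by elementwise maximum expression.
#'
#' @param matrix Numeric matrix with foreign identifiers as row names.
#' @param ortholog_map Named character vector, foreign ID to gene symbol
#'   (see [read_ortholog_map()]).
#' @param source_label Passed to [celltype_expression_table()].
#' @return A [celltype_expression_table()].
#' @export
map_orthologs <- function(matrix, ortholog_map, source_label = "external") {
  if (!length(ortholog_map)) stop("ortholog map is empty")
  mapped <- ortholog_map[rownames(matrix)]
  keep <- !is.na(mapped)
  n_drop <- sum(!keep)
  if (n_drop)
    message(n_drop, " unmapped identifier(s) dropped")
  m <- matrix[keep, , drop = FALSE]
  genes <- unname(mapped[keep])
  collapsed <- do.call(rbind, lapply(split(seq_len(nrow(m)), genes),
                                     function(i)
                                       apply(m[i, , drop = FALSE], 2, max)))
  celltype_expression_table(collapsed, source_label)
}

#' Tally external expression support for cell-type assignments
#'
#' For each cell type, counts how many genes assigned to it by the
#' deconvolution models show expression above `threshold` in that cell
#' type in an external cell-type-resolved table. Genes absent from the
#' table are excluded from the denominator; assignments are reduced to
#' unique gene symbols.
#'
#' @param assignments Data frame with columns `gene` and `cell_type`
#'   (e.g. derived from [as.data.frame.psea_models()] rows), or a named
#'   character vector gene -> cell type.
#' @param table A [celltype_expression_table()].
#' @param threshold Minimum expression in normalized units counted as
#'   detected (default 100).
#' @return Data frame per cell type: `cell_type`, `n_assigned`,
#'   `n_in_table`, `n_supported`, `fraction`, `label` formatted as
#'   `"81% (210/259)"`. Cell types with no assigned gene in the table get
#'   `NA` fraction.
#' @export
tally_expression_support <- function(assignments, table, threshold = 100) {
  if (!is.data.frame(assignments))
    assignments <- data.frame(gene = names(assignments),
                              cell_type = unname(assignments),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "cell_type") %in% names(assignments)))
  assignments <- unique(assignments[!is.na(assignments$gene),
                                    c("gene", "cell_type")])
  types <- unique(assignments$cell_type)
  res <- data.frame(cell_type = types, n_assigned = NA_integer_,
                    n_in_table = NA_integer_, n_supported = NA_integer_,
                    fraction = NA_real_, label = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(types)) {
    ct <- types[i]
    genes <- unique(assignments$gene[assignments$cell_type == ct])
    present <- genes[genes %in% rownames(table)]
    res$n_assigned[i] <- length(genes)
    res$n_in_table[i] <- length(present)
    if (!ct %in% colnames(table)) {
      res$n_supported[i] <- NA_integer_
      next
    }
    if (length(present)) {
      res$n_supported[i] <- sum(table[present, ct] > threshold)
      res$fraction[i] <- res$n_supported[i] / length(present)
      res$label[i] <- sprintf("%d%% (%d/%d)",
                              round(100 * res$fraction[i]),
                              res$n_supported[i], length(present))
    } else {
      res$n_supported[i] <- 0L
    }
  }
  res
}

#' Direction concordance with external differential-expression tables
#'
#' Tallies, gene by gene, whether independent external studies (e.g.
#' laser-capture-microdissection comparisons) detected the same gene as
#' differentially expressed in the same direction. A source validates a
#' gene when the gene is present, its external p-value is below `alpha`,
#' its fold change is non-missing, and the fold-change sign matches the
#' deconvolution's.
#'
#' @param psea_de A `psea_de` table (columns `gene`,
#'   `log2_fold_change`).
#' @param externals Named list of data frames with columns `gene`,
#'   `pvalue`, `log_fold_change`.
#' @param alpha External p-value cutoff (default 0.05).
#' @return A list: `matrix` (gene-by-source logical), `n_validated_ge1`,
#'   `n_validated_ge2`, `n_genes`.
#' @export
direction_concordance <- function(psea_de, externals, alpha = 0.05) {
  genes <- unique(psea_de$gene[!is.na(psea_de$gene)])
  fc <- psea_de$log2_fold_change[match(genes, psea_de$gene)]
  if (is.null(names(externals)))
    names(externals) <- paste0("source", seq_along(externals))
  mat <- matrix(FALSE, length(genes), length(externals),
                dimnames = list(genes, names(externals)))
  for (s in names(externals)) {
    ext <- externals[[s]]
    idx <- match(genes, ext$gene)
    ok <- !is.na(idx)
    p <- ext$pvalue[idx[ok]]
    efc <- ext$log_fold_change[idx[ok]]
    mat[ok, s] <- !is.na(p) & p < alpha & !is.na(efc) &
      sign(efc) == sign(fc[ok]) & sign(efc) != 0
  }
  nv <- rowSums(mat)
  list(matrix = mat, n_validated_ge1 = sum(nv >= 1),
       n_validated_ge2 = sum(nv >= 2), n_genes = length(genes))
}
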