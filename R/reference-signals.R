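#' Marker probeset correlation QC
#'
#' Checks that the probesets chosen as markers for a cell type report
#' concordant signals, and that markers of different cell types do not.
#' The within-type score for a cell type is the mean of the pairwise
#' Pearson correlations (across samples) among its marker probesets; a
#' cell type is usable when this exceeds `within_min`. The between-type
#' score for a pair of cell types is the mean correlation over all cross
#' pairs of their probesets; pairs above `between_max` are reported as
#' warnings but do not gate usability, matching the practice of
#' proceeding with the usable subset of cell types rather than aborting.
#'
#' @param dataset An [expression_dataset()].
#' @param markers A [marker_set()].
#' @param within_min Minimum within-type mean correlation for a usable
#'   reference signal (default 0.5).
#' @param between_max Advisory maximum between-type mean correlation
#'   (default 0.05).
#' @param use_absolute Use absolute instead of signed correlations for the
#'   between-type score (default signed, as the thresholds are quoted on
#'   raw correlations).
#' @return A list of class `psea_marker_qc`: `within` (named numeric; NA
#'   when a type has a single probeset, which passes vacuously with a
#'   warning), `between` (data frame of type pairs and mean correlations),
#'   `usable_flags` (named logical), `excluded` (zero-variance probesets),
#'   `failing_pairs` (between-type pairs exceeding `between_max`).
#' @export
qc_marker_correlations <- function(dataset, markers, within_min = 0.5,
                                   between_max = 0.05,
                                   use_absolute = FALSE) {
  check_markers(markers, dataset)
  mk <- unclass(markers)
  types <- names(mk)

  excluded <- character(0)
  rows <- lapply(mk, function(m) {
    x <- dataset$matrix[names(m), , drop = FALSE]
    v <- apply(x, 1, stats::var)
    zv <- rownames(x)[v == 0 | is.na(v)]
    excluded <<- c(excluded, zv)
    x[!(rownames(x) %in% zv), , drop = FALSE]
  })

  within <- vapply(types, function(ct) {
    x <- rows[[ct]]
    if (nrow(x) < 2) return(NA_real_)
    cm <- stats::cor(t(x))
    mean(cm[upper.tri(cm)])
  }, numeric(1))

  pair_idx <- if (length(types) > 1) utils::combn(types, 2) else
    matrix(character(0), 2, 0)
  between <- data.frame(type1 = pair_idx[1, ], type2 = pair_idx[2, ],
                        mean_cor = rep(NA_real_, ncol(pair_idx)),
                        stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pair_idx))) {
    x1 <- rows[[pair_idx[1, p]]]
    x2 <- rows[[pair_idx[2, p]]]
    if (!nrow(x1) || !nrow(x2)) next
    cc <- stats::cor(t(x1), t(x2))
    if (use_absolute) cc <- abs(cc)
    between$mean_cor[p] <- mean(cc)
  }

  usable <- !is.na(within) & within > within_min
  if (any(is.na(within))) {
    usable[is.na(within)] <- TRUE
    warning("cell type(s) with <2 marker probesets pass within-type QC ",
            "vacuously: ", paste(types[is.na(within)], collapse = ", "))
  }
  names(usable) <- types

  structure(list(within = within, between = between,
                 usable_flags = usable, excluded = unique(excluded),
                 failing_pairs = between[!is.na(between$mean_cor) &
                                           between$mean_cor > between_max, ],
                 within_min = within_min, between_max = between_max),
            class = "psea_marker_qc")
}

#' @export
print.psea_marker_qc <- function(x, ...) {
  cat("Marker correlation QC (within-type threshold >",
      x$within_min, ")\n")
  for (ct in names(x$within))
    cat(sprintf("  %-16s within = %s  usable = %s\n", ct,
                formatC(x$within[ct], digits = 3, format = "f"),
                x$usable_flags[ct]))
  if (nrow(x$failing_pairs)) {
    cat("  between-type pairs above", x$between_max, ":\n")
    for (i in seq_len(nrow(x$failing_pairs)))
      cat(sprintf("    %s ~ %s: %.3f\n", x$failing_pairs$type1[i],
                  x$failing_pairs$type2[i], x$failing_pairs$mean_cor[i]))
  }
  if (length(x$excluded))
    cat("  zero-variance probesets excluded:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Build per-cell-type reference expression signals
#'
#' For each marker probeset, expression values are scaled so their
#' across-sample mean is exactly 100 (equal weight per probeset); scaled
#' probesets reporting the same marker gene are averaged into a gene
#' measure; gene measures within a cell type are averaged into that cell
#' type's reference signal. The averaging order (probesets to gene, genes
#' to cell type) matters when genes contribute unequal probeset counts.
#' Each resulting column has mean exactly 100 and, under the linear mixing
#' model with faithful markers, is proportional to the latent abundance of
#' its cell population.
#'
#' @param dataset An [expression_dataset()].
#' @param markers A [marker_set()].
#' @param usable_only Drop cell types flagged unusable by `qc` (default
#'   `FALSE`).
#' @param qc Optional [qc_marker_correlations()] result; computed on the
#'   fly when `usable_only = TRUE` and not supplied.
#' @return A sample-by-cell-type numeric matrix of class
#'   `reference_signals`.
#' @export
build_reference_signals <- function(dataset, markers, usable_only = FALSE,
                                    qc = NULL) {
  check_markers(markers, dataset)
  mk <- unclass(markers)
  if (usable_only) {
    if (is.null(qc)) qc <- qc_marker_correlations(dataset, markers)
    mk <- mk[names(mk)[qc$usable_flags[names(mk)]]]
    if (!length(mk)) stop("no usable cell types after QC")
  }
  cols <- list()
  for (ct in names(mk)) {
    m <- mk[[ct]]
    scaled_by_gene <- list()
    for (ps in names(m)) {
      x <- dataset$matrix[ps, ]
      mu <- mean(x)
      if (mu == 0) {
        warning("all-zero marker probeset excluded: ", ps)
        next
      }
      g <- m[[ps]]
      scaled_by_gene[[g]] <- rbind(scaled_by_gene[[g]], 100 * x / mu)
    }
    if (!length(scaled_by_gene)) {
      warning("cell type ", ct, " has no usable marker probesets; ",
              "reference column omitted")
      next
    }
    gene_measures <- t(vapply(scaled_by_gene, colMeans,
                              numeric(ncol(dataset$matrix))))
    cols[[ct]] <- colMeans(gene_measures)
  }
  if (!length(cols)) stop("no reference signals could be built")
  refs <- do.call(cbind, cols)
  rownames(refs) <- colnames(dataset$matrix)
  structure(refs, class = c("reference_signals", class(refs)))
}

#' Write reference signals to TSV
#'
#' @param refs A `reference_signals` matrix.
#' @param path Output TSV path (sample rows, cell-type columns).
#' @return Invisibly, `refs`.
#' @export
write_reference_signals <- function(refs, path) {
  utils::write.table(data.frame(sample_id = rownames(refs),
                                unclass(refs), check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(refs)
}
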