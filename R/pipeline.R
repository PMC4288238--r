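#' Run the full deconvolution workflow on a dataset
#'
#' Orchestrates the standard analysis end to end: marker QC, reference
#' signal construction, model fitting with AIC subset selection and
#' quality filtering, cell-type-specific differential expression, and the
#' composition-naive baseline. With `mode = "single_type"` the joint
#' four-cell-type modeling is replaced by the single-cell-type fallback
#' restricted to `target_types` (used when some reference signals fail
#' QC). Per-stage counts are logged via `message()`.
#'
#' @param dataset An [expression_dataset()].
#' @param markers A [marker_set()].
#' @param mode `"full"` (joint AIC-selected models) or `"single_type"`.
#' @param target_types Cell types modeled in single-type mode; defaults
#'   to the QC-usable types.
#' @param alpha Unadjusted p-value cutoff for reported DE tables.
#' @param filters A [psea_filters()] list.
#' @param standard_de Also run the composition-naive baseline (default
#'   `TRUE`).
#' @param out_dir Optional directory; when given, all tables are written
#'   as TSV via [write_psea_outputs()].
#' @return A list of class `psea_run`: `qc`, `refs`, `models` (full mode
#'   only), `de`, `standard` (or `NULL`), `mode`, `alpha`.
#' @export
psea_pipeline <- function(dataset, markers,
                          mode = c("full", "single_type"),
                          target_types = NULL, alpha = 0.05,
                          filters = psea_filters(),
                          standard_de = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  check_markers(markers, dataset)
  qc <- qc_marker_correlations(dataset, markers)
  refs <- build_reference_signals(dataset, markers)
  models <- NULL
  if (mode == "full") {
    # differential testing runs on every AIC-selected model: the
    # augmented-model re-assessment gates the DE table, while the base
    # filters gate the expression-assignment table (run$models)
    fitted <- run_psea_models(dataset, refs, markers, filters,
                              keep_failing = TRUE)
    de <- run_psea_de(fitted, dataset, refs, alpha = alpha,
                      filters = filters)
    models <- passing_models(fitted)
  } else {
    if (is.null(target_types))
      target_types <- names(qc$usable_flags)[qc$usable_flags]
    de <- run_single_type_psea(dataset, refs, target_types = target_types,
                               markers = markers, alpha = alpha,
                               filters = filters)
  }
  std <- if (standard_de) run_standard_de(dataset) else NULL
  run <- structure(list(qc = qc, refs = refs, models = models, de = de,
                        standard = std, mode = mode, alpha = alpha),
                   class = "psea_run")
  if (!is.null(out_dir)) write_psea_outputs(run, out_dir,
                                            dataset = dataset)
  run
}

#' Write pipeline outputs to a directory
#'
#' Writes the QC report, reference signals, model table, cell-type
#' differential-expression table and (when present) the standard-analysis
#' table as TSV files.
#'
#' @param run A `psea_run` from [psea_pipeline()].
#' @param dir Output directory (created if needed).
#' @param dataset Optional dataset used to annotate model tables with
#'   gene symbols.
#' @return Invisibly, the vector of files written.
#' @export
write_psea_outputs <- function(run, dir, dataset = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  qc_df <- data.frame(cell_type = names(run$qc$within),
                      within_mean_cor = unname(run$qc$within),
                      usable = unname(run$qc$usable_flags))
  wt(qc_df, "marker_qc.tsv")
  wt(run$qc$between, "marker_qc_between.tsv")
  write_reference_signals(run$refs, file.path(dir,
                                              "reference_signals.tsv"))
  files <- c(files, file.path(dir, "reference_signals.tsv"))
  if (!is.null(run$models))
    wt(as.data.frame(run$models, dataset = dataset), "psea_models.tsv")
  wt(as.data.frame(run$de), "psea_de.tsv")
  wt(as.data.frame(attr(run$de, "all_tests")), "psea_de_all_tests.tsv")
  if (!is.null(run$standard)) wt(run$standard, "standard_de.tsv")
  invisible(files)
}

#' @export
print.psea_run <- function(x, ...) {
  cat("psea_run (mode =", x$mode, ")\n")
  print(x$qc)
  if (!is.null(x$models)) print(x$models)
  cat("DE calls at p <", x$alpha, ":", nrow(x$de), "\n")
  invisible(x)
}
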