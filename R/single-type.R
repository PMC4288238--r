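#' Screen probesets for single-cell-type expression
#'
#' The fallback mode for tissues where some reference signals are
#' degenerate: instead of modeling all four cell populations jointly,
#' analysis is restricted to probesets that report expression exclusively
#' in a single cell type. A probeset is assigned to a cell type when its
#' Pearson correlation with that type's reference signal exceeds `high`
#' (default 0.8) and its correlation with each of the other reference
#' signals is below `low` (default 0.2). Screening uses all available
#' reference columns, including ones unusable for joint modeling: the
#' exclusivity requirement needs them.
#'
#' @param dataset An [expression_dataset()].
#' @param refs Reference signals (all cell types).
#' @param high Minimum correlation with the assigned type's signal.
#' @param low Maximum correlation with every other type's signal.
#' @param use_absolute Apply the `low` rule to absolute correlations
#'   (default signed, as assignment itself requires a positive r > 0.8).
#' @return Data frame of class `single_type_screen`: probeset, one
#'   correlation column per cell type (`r_<type>`), `assigned_type` (NA
#'   when unassigned) and `reason`.
#' @export
screen_single_type <- function(dataset, refs, high = 0.8, low = 0.2,
                               use_absolute = FALSE) {
  if (!identical(rownames(refs), colnames(dataset$matrix)))
    stop("reference signals and dataset samples are not aligned")
  types <- colnames(refs)
  rv <- apply(dataset$matrix, 1, stats::var)
  cors <- matrix(NA_real_, nrow(dataset$matrix), length(types),
                 dimnames = list(rownames(dataset$matrix), types))
  nz <- rv > 0
  if (any(nz))
    cors[nz, ] <- stats::cor(t(dataset$matrix[nz, , drop = FALSE]),
                             unclass(refs))
  assigned <- rep(NA_character_, nrow(cors))
  reason <- rep(NA_character_, nrow(cors))
  reason[!nz] <- "zero variance"
  for (i in which(nz)) {
    r <- cors[i, ]
    others <- if (use_absolute) abs(r) else r
    hit <- which(r > high)
    if (length(hit) == 1 && all(others[-hit] < low))
      assigned[i] <- types[hit]
    else if (length(hit) > 1)
      reason[i] <- "high correlation with multiple cell types"
    else if (length(hit) == 1)
      reason[i] <- "not exclusive: another signal above the low threshold"
    else
      reason[i] <- "no reference signal above the high threshold"
  }
  out <- data.frame(probeset_id = rownames(cors), cors,
                    assigned_type = assigned, reason = reason,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1 + seq_along(types)] <- paste0("r_", types)
  rownames(out) <- NULL
  structure(out, class = c("single_type_screen", class(out)),
            high = high, low = low)
}

#' Single-cell-type expression deconvolution and differential expression
#'
#' For each probeset assigned to one of `target_types` by
#' [screen_single_type()], fits the single-regressor model
#' `expression ~ intercept + reference signal` and tests differential
#' expression with the corresponding auxiliary regressor. As in the joint
#' mode, the quality filters re-assessed on the auxiliary-augmented model
#' gate the reported DE table. Marker probesets are excluded from the
#' output.
#'
#' @param dataset An [expression_dataset()].
#' @param refs Reference signals (all cell types; screening needs them
#'   even when only a subset is model-quality).
#' @param groups Per-sample labels (defaults to the dataset's).
#' @param target_types Cell types to model (e.g. `c("neuron",
#'   "microglia")` when the glial signals are degenerate).
#' @param markers Optional [marker_set()] whose probesets are removed.
#' @param screen Optional precomputed [screen_single_type()] result.
#' @param alpha Unadjusted p-value cutoff for the reported table.
#' @param filters A [psea_filters()] list.
#' @param high,low Screening thresholds, passed to
#'   [screen_single_type()] when `screen` is not supplied.
#' @return A `psea_de` data frame as in [run_psea_de()]; the screen is
#'   attached as `attr(result, "screen")`.
#' @export
run_single_type_psea <- function(dataset, refs, groups = dataset$groups,
                                 target_types = colnames(refs),
                                 markers = NULL, screen = NULL,
                                 alpha = 0.05, filters = psea_filters(),
                                 high = 0.8, low = 0.2) {
  if (is.null(screen))
    screen <- screen_single_type(dataset, refs, high = high, low = low)
  stopifnot(all(target_types %in% colnames(refs)))
  sel <- !is.na(screen$assigned_type) &
    screen$assigned_type %in% target_types
  if (!is.null(markers))
    sel <- sel & !(screen$probeset_id %in% marker_probesets(markers))

  models <- list()
  n_pass <- 0L
  for (i in which(sel)) {
    ps <- screen$probeset_id[i]
    ct <- screen$assigned_type[i]
    m <- select_model_aic(dataset$matrix[ps, ], refs, usable = ct,
                          probeset_id = ps)
    if (inherits(m, "psea_skip")) next
    m <- apply_quality_filters(m, filters)
    if (m$overall_pass) n_pass <- n_pass + 1L
    models[[ps]] <- m
  }
  models_obj <- structure(list(
    models = models,
    counts = c(probesets_in = sum(sel), skipped = NA, fitted = sum(sel),
               passing = n_pass),
    filters = filters), class = "psea_models")
  out <- run_psea_de(models_obj, dataset, refs, groups, alpha, filters)
  attr(out, "screen") <- screen
  out
}

#' Concordance of two differential-expression tables
#'
#' Fraction of the differentially expressed probesets in the standard
#' (joint four-cell-type) table that are also detected by the alternative
#' (single-cell-type) table, computed on probeset IDs, both pooled and per
#' cell type.
#'
#' @param std_results,alt_results `psea_de` data frames from the same
#'   dataset.
#' @return List with `pooled` (fraction, NA when the standard table is
#'   empty), `by_cell_type` (named numeric), `n_std`, `n_shared`.
#' @export
concordance_with_standard <- function(std_results, alt_results) {
  std_ps <- unique(std_results$probeset_id)
  alt_ps <- unique(alt_results$probeset_id)
  pooled <- if (length(std_ps)) length(intersect(std_ps, alt_ps)) /
    length(std_ps) else NA_real_
  by_ct <- vapply(split(std_results$probeset_id, std_results$cell_type),
                  function(ps) {
                    ps <- unique(ps)
                    if (!length(ps)) return(NA_real_)
                    length(intersect(ps, alt_ps)) / length(ps)
                  }, numeric(1))
  list(pooled = pooled, by_cell_type = by_ct,
       n_std = length(std_ps),
       n_shared = length(intersect(std_ps, alt_ps)))
}
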