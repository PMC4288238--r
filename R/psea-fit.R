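#' Quality-filter thresholds for expression models
#'
#' The defaults are the published gates for accepting a deconvolution
#' model: overall regression F-test p < 0.05, adjusted R-squared > 0.6,
#' Shapiro-Wilk normality of residuals p > 0.01, intercept magnitude at
#' most half the probeset's mean expression, and no negative cell-type
#' coefficients (a negative cell-type-specific expression level is
#' physically meaningless and the model is discarded rather than
#' constrained).
#'
#' @param f_alpha Maximum F-test p-value.
#' @param min_adj_r2 Minimum adjusted R-squared.
#' @param shapiro_alpha Minimum Shapiro-Wilk p-value on residuals.
#' @param max_intercept_frac Maximum |intercept| as a fraction of the
#'   probeset's mean expression.
#' @param require_nonneg Require all cell-type coefficients >= 0.
#' @return A list of class `psea_filters`.
#' @export
psea_filters <- function(f_alpha = 0.05, min_adj_r2 = 0.6,
                         shapiro_alpha = 0.01, max_intercept_frac = 0.5,
                         require_nonneg = TRUE) {
  stopifnot(f_alpha > 0, f_alpha <= 1, min_adj_r2 <= 1,
            shapiro_alpha >= 0, shapiro_alpha <= 1,
            max_intercept_frac >= 0)
  structure(list(f_alpha = f_alpha, min_adj_r2 = min_adj_r2,
                 shapiro_alpha = shapiro_alpha,
                 max_intercept_frac = max_intercept_frac,
                 require_nonneg = require_nonneg),
            class = "psea_filters")
}

# Relative RSS floor used inside the AIC only: exact fits leave residuals
# at machine-rounding scale whose log ratios are meaningless, so all
# exact fits score equally and compare by parameter count.
AIC_RSS_FLOOR <- 1e-12

#' Ordinary least squares fit of expression on reference signals
#'
#' Fits `y = intercept + X b + e` by QR decomposition and returns the
#' statistics the quality filters need. The AIC follows the
#' `n log(RSS/n) + 2 edf` convention (`edf` = number of coefficients
#' including the intercept, + 1 for the variance); only AIC differences
#' between candidate models on the same response are meaningful. The
#' F-test is the overall regression test against the intercept-only model
#' and `adj_r2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param y Numeric response (per-sample expression of one probeset).
#' @param X Numeric matrix of regressor columns (reference signals),
#'   without intercept; may have zero columns.
#' @return A list of class `psea_fit` with elements `intercept`,
#'   `coefficients` (named by regressor), `fitted`, `residuals`, `rss`,
#'   `aic`, `f_pvalue`, `adj_r2`, `coef_se`, `coef_pvalues`, `ok` (FALSE
#'   for rank-deficient designs).
#' @export
fit_ols <- function(y, X) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (n <= p + 1) stop("need more samples than coefficients")
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(Xd)
  if (qr_d$rank < ncol(Xd))
    return(structure(list(ok = FALSE), class = "psea_fit"))
  coefs <- qr.coef(qr_d, y)
  fitted <- drop(Xd %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p - 1
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_res else NA_real_
  f_pvalue <- if (p == 0) 1 else if (tss == 0) NA_real_ else {
    fstat <- ((tss - rss) / p) / (rss / df_res)
    stats::pf(fstat, p, df_res, lower.tail = FALSE)
  }
  rss_floor <- AIC_RSS_FLOOR * max(tss, .Machine$double.xmin)
  aic <- n * log(max(rss, rss_floor) / n) + 2 * (p + 2)
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  names(se) <- names(coefs)
  tstat <- coefs / se
  pvals <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  structure(list(
    ok = TRUE, intercept = unname(coefs[1]),
    coefficients = coefs[-1], fitted = fitted, residuals = res,
    rss = rss, tss = tss, aic = aic, f_pvalue = f_pvalue,
    adj_r2 = adj_r2, coef_se = se[-1], coef_pvalues = pvals[-1],
    intercept_se = se[1], n = n
  ), class = "psea_fit")
}

# Shapiro-Wilk on residuals; near-constant residuals (exact fits) carry no
# evidence against normality, so they return NA (treated as a pass).
shapiro_p <- function(res) {
  if (diff(range(res)) < 1e-10 * max(1, max(abs(res))))
    return(NA_real_)
  out <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e)
    NA_real_)
  out
}

# All non-empty subsets of `types` ordered by size then by the fixed
# cell-type order, so the first minimal-AIC candidate wins ties.
candidate_subsets <- function(types) {
  out <- list()
  for (size in seq_along(types))
    out <- c(out, utils::combn(types, size, simplify = FALSE))
  out
}

# Marker for probesets that cannot be modeled, with the recorded reason.
psea_skip <- function(reason, probeset_id = NA_character_) {
  structure(list(reason = reason, probeset_id = probeset_id),
            class = "psea_skip")
}

# The candidate design matrices are identical for every probeset of a
# dataset, so their QR decompositions are computed once and shared.
design_qr_cache <- function(refs, usable = colnames(refs)) {
  lapply(candidate_subsets(usable), function(subset) {
    Xd <- cbind(1, refs[, subset, drop = FALSE])
    q <- qr(Xd)
    list(subset = subset, qr = q, ok = q$rank == ncol(Xd))
  })
}

#' Select the best expression model by AIC
#'
#' Evaluates ordinary least squares fits of a probeset's expression on
#' every non-empty subset of the usable reference-signal columns (at most
#' 15 candidates for four cell types) and returns the minimum-AIC model.
#' Ties (within 1e-8) are broken in favor of fewer regressors, then by the
#' fixed cell-type order of the reference columns. Exhaustive enumeration
#' is deterministic and at least as good as a stepwise search under the
#' same criterion. The intercept-only model is not a candidate, but its
#' RSS anchors the F-test.
#'
#' @param y Per-sample expression of one probeset (aligned with
#'   `rownames(refs)`).
#' @param refs A `reference_signals` matrix (or any sample-by-cell-type
#'   matrix).
#' @param usable Cell types to consider (default all columns of `refs`).
#' @param probeset_id Optional ID stored on the result.
#' @param .cache Precomputed candidate-design QR decompositions (internal;
#'   the candidate designs are shared by all probesets of a dataset).
#' @return A list of class `psea_model`: `probeset_id`, `regressors`,
#'   `intercept`, `coefficients`, `aic`, `f_pvalue`, `adj_r2`,
#'   `shapiro_pvalue`, `mean_expression`, `fit`. Zero-variance responses
#'   and responses with no fittable subset return a `psea_skip` object
#'   carrying the reason instead.
#' @export
select_model_aic <- function(y, refs, usable = colnames(refs),
                             probeset_id = NA_character_,
                             .cache = NULL) {
  if (stats::var(y) == 0)
    return(psea_skip("zero-variance expression", probeset_id))
  if (is.null(.cache)) .cache <- design_qr_cache(refs, usable)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rss_floor <- AIC_RSS_FLOOR * max(tss, .Machine$double.xmin)
  best <- NULL
  best_aic <- Inf
  for (cand in .cache) {
    if (!cand$ok) next
    rss <- sum(qr.resid(cand$qr, y)^2)
    aic <- n * log(max(rss, rss_floor) / n) + 2 * (length(cand$subset) + 2)
    if (aic < best_aic - 1e-8) {
      best <- cand
      best_aic <- aic
    }
  }
  if (is.null(best))
    return(psea_skip("no fittable regressor subset", probeset_id))
  fit <- fit_ols(y, refs[, best$subset, drop = FALSE])
  structure(list(
    probeset_id = probeset_id, regressors = best$subset,
    intercept = fit$intercept, coefficients = fit$coefficients,
    aic = fit$aic, f_pvalue = fit$f_pvalue, adj_r2 = fit$adj_r2,
    shapiro_pvalue = shapiro_p(fit$residuals),
    mean_expression = mean(y), fit = fit
  ), class = "psea_model")
}

#' Apply quality-of-fit filters to a selected model
#'
#' Adds per-criterion pass flags and the overall verdict to a
#' [select_model_aic()] result. A model passes overall when the F-test,
#' adjusted R-squared, residual-normality, intercept-magnitude and
#' coefficient-sign criteria all pass. The sign rule applies to the
#' cell-type coefficients only; the intercept has its own magnitude rule.
#' An NA Shapiro p-value (machine-exact fit) passes.
#'
#' @param model A `psea_model`.
#' @param filters A [psea_filters()] list.
#' @return The model with `pass_flags` (named logical) and `overall_pass`.
#' @export
apply_quality_filters <- function(model, filters = psea_filters()) {
  stopifnot(inherits(model, "psea_model"))
  flags <- c(
    f_test = is.finite(model$f_pvalue) &&
      model$f_pvalue < filters$f_alpha,
    adj_r2 = is.finite(model$adj_r2) &&
      model$adj_r2 > filters$min_adj_r2,
    shapiro = is.na(model$shapiro_pvalue) ||
      model$shapiro_pvalue > filters$shapiro_alpha,
    intercept = abs(model$intercept) <=
      filters$max_intercept_frac * model$mean_expression,
    coef_sign = !filters$require_nonneg ||
      min(model$coefficients) >= 0
  )
  model$pass_flags <- flags
  model$overall_pass <- all(flags)
  model
}

#' Fit and filter expression models for a whole dataset
#'
#' Runs [select_model_aic()] and [apply_quality_filters()] on every
#' probeset of the dataset, excluding the marker probesets that the
#' reference signals were built from, and reports per-stage counts.
#'
#' @param dataset An [expression_dataset()].
#' @param refs Reference signals from [build_reference_signals()];
#'   `rownames(refs)` must equal the dataset's sample IDs.
#' @param markers Optional [marker_set()] whose probesets are removed from
#'   the output tables.
#' @param filters A [psea_filters()] list.
#' @param keep_failing Keep models failing the quality filters in the
#'   result (flagged); default `FALSE` returns passing models only.
#' @return A list of class `psea_models`: `models` (passing, or all when
#'   `keep_failing`), `counts` (probesets in, skipped, fitted, passing),
#'   `skipped` (data frame of probeset, reason).
#' @export
run_psea_models <- function(dataset, refs, markers = NULL,
                            filters = psea_filters(),
                            keep_failing = FALSE) {
  if (!identical(rownames(refs), colnames(dataset$matrix)))
    stop("reference signals and dataset samples are not aligned")
  ps <- rownames(dataset$matrix)
  if (!is.null(markers)) ps <- setdiff(ps, marker_probesets(markers))
  models <- vector("list", length(ps))
  skipped <- list()
  n_pass <- 0L
  cache <- design_qr_cache(refs)
  for (i in seq_along(ps)) {
    y <- dataset$matrix[ps[i], ]
    m <- select_model_aic(y, refs, probeset_id = ps[i], .cache = cache)
    if (inherits(m, "psea_skip")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(probeset_id = ps[i], reason = m$reason,
                   stringsAsFactors = FALSE)
      next
    }
    m <- apply_quality_filters(m, filters)
    if (m$overall_pass) n_pass <- n_pass + 1L
    models[[i]] <- m
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (!keep_failing)
    models <- models[vapply(models, `[[`, logical(1), "overall_pass")]
  names(models) <- vapply(models, `[[`, character(1), "probeset_id")
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(probeset_id = character(0), reason = character(0))
  counts <- c(probesets_in = length(ps), skipped = nrow(skipped),
              fitted = length(ps) - nrow(skipped), passing = n_pass)
  message(sprintf(
    "PSEA models: %d probesets in, %d skipped, %d fitted, %d passing",
    counts[1], counts[2], counts[3], counts[4]))
  structure(list(models = models, counts = counts, skipped = skipped,
                 filters = filters),
            class = "psea_models")
}

#' Subset a model collection to quality-passing models
#'
#' @param models A `psea_models` result fitted with `keep_failing = TRUE`.
#' @return A `psea_models` object containing only models with
#'   `overall_pass = TRUE`.
#' @export
passing_models <- function(models) {
  stopifnot(inherits(models, "psea_models"))
  models$models <- models$models[
    vapply(models$models, `[[`, logical(1), "overall_pass")]
  models
}

#' @export
print.psea_models <- function(x, ...) {
  cat("psea_models:", x$counts["fitted"], "fitted,",
      x$counts["passing"], "passing quality filters\n")
  invisible(x)
}

#' Tabulate fitted expression models
#'
#' @param x A `psea_models` result.
#' @param dataset Optional [expression_dataset()] used to add gene symbols.
#' @param ... Unused.
#' @return Data frame with one row per model: probeset, gene, regressors
#'   (comma-separated), intercept, per-cell-type coefficients, AIC, F
#'   p-value, adjusted R-squared, Shapiro p-value, pass flags.
#' @export
as.data.frame.psea_models <- function(x, dataset = NULL, ...) {
  if (!length(x$models))
    return(data.frame(probeset_id = character(0)))
  types <- unique(unlist(lapply(x$models, `[[`, "regressors")))
  rows <- lapply(x$models, function(m) {
    coefs <- stats::setNames(rep(NA_real_, length(types)), types)
    coefs[m$regressors] <- m$coefficients
    out <- data.frame(probeset_id = m$probeset_id,
                      regressors = paste(m$regressors, collapse = ","),
                      intercept = m$intercept, t(coefs),
                      aic = m$aic, f_pvalue = m$f_pvalue,
                      adj_r2 = m$adj_r2,
                      shapiro_pvalue = m$shapiro_pvalue,
                      mean_expression = m$mean_expression,
                      overall_pass = m$overall_pass,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(dataset))
    tab <- cbind(tab[, 1, drop = FALSE],
                 gene = gene_of(dataset, tab$probeset_id),
                 tab[, -1, drop = FALSE])
  tab
}
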