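#' Standard (composition-naive) two-group differential expression
#'
#' Per-probeset two-group comparison on `log2(x + 1)`-transformed values,
#' the baseline the deconvolution is compared against. With
#' `moderated = TRUE` (default) the per-probeset variances are shrunk by
#' empirical Bayes via limma's moderated t-statistic; with
#' `moderated = FALSE` an ordinary equal-variance t-test from the same
#' linear model is used, which has no external dependency and an exact
#' small-sample null. Benjamini-Hochberg FDR is computed across all
#' probesets.
#'
#' This analysis is blind to tissue composition: a shift in cell-type
#' proportions between groups changes bulk expression and is reported as
#' differential expression even when no cell changes its per-cell
#' expression.
#'
#' @param dataset An [expression_dataset()].
#' @param groups Per-sample labels (defaults to the dataset's).
#' @param moderated Use empirical-Bayes moderated t (default `TRUE`).
#' @return Data frame: `probeset_id`, `gene`, `log2_fold_change`
#'   (disease minus control), `t_statistic`, `pvalue`, `fdr`. Probesets
#'   with zero variance within both groups get `NA` statistics (flagged
#'   via `zero_variance`).
#' @export
run_standard_de <- function(dataset, groups = dataset$groups,
                            moderated = TRUE) {
  g <- factor(as.character(groups), levels = c("control", "disease"))
  if (any(table(g) < 2)) stop("need at least 2 samples per group")
  ylog <- log2(dataset$matrix + 1)
  design <- cbind(Intercept = 1, disease = as.numeric(g == "disease"))
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(ylog, design))
    tab <- data.frame(
      probeset_id = rownames(ylog),
      log2_fold_change = fit$coefficients[, "disease"],
      t_statistic = fit$t[, "disease"],
      pvalue = fit$p.value[, "disease"],
      stringsAsFactors = FALSE)
  } else {
    n <- ncol(ylog)
    df_res <- n - 2
    mc <- rowMeans(ylog[, g == "control", drop = FALSE])
    md <- rowMeans(ylog[, g == "disease", drop = FALSE])
    fitted <- cbind(mc, md)[, as.integer(g)]
    rss <- rowSums((ylog - fitted)^2)
    s2 <- rss / df_res
    se <- sqrt(s2 * (1 / sum(g == "control") + 1 / sum(g == "disease")))
    tstat <- (md - mc) / se
    tab <- data.frame(
      probeset_id = rownames(ylog), log2_fold_change = md - mc,
      t_statistic = tstat,
      pvalue = 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  zero_var <- !is.finite(tab$t_statistic)
  tab$pvalue[zero_var] <- NA_real_
  tab$t_statistic[zero_var] <- NA_real_
  tab$zero_variance <- zero_var
  tab$fdr <- stats::p.adjust(tab$pvalue, method = "BH")
  tab$gene <- gene_of(dataset, tab$probeset_id)
  rownames(tab) <- NULL
  tab[, c("probeset_id", "gene", "log2_fold_change", "t_statistic",
          "pvalue", "fdr", "zero_variance")]
}

#' Paired comparison of deconvolved and standard differential expression
#'
#' For each probeset shared between a cell-type-specific
#' differential-expression table and a standard two-group table, builds
#' the data behind the side-by-side report: the per-sample expression
#' versus reference-signal scatter with per-group regression slopes (the
#' deconvolution view) and the per-group expression distributions (the
#' standard view), plus a classification of agreement.
#'
#' Classification (at `alpha` on the deconvolution's unadjusted p and on
#' the standard analysis's FDR): `concordant` (both significant, same
#' direction), `psea_only`, `standard_only`, `sign_discordant` (both
#' significant, opposite directions), `neither`.
#'
#' @param psea_results A `psea_de` table (typically the unfiltered
#'   `attr(. , "all_tests")` if non-significant probesets should be
#'   classifiable).
#' @param standard_results Output of [run_standard_de()].
#' @param dataset The shared [expression_dataset()].
#' @param refs Reference signals.
#' @param cell_type Cell type whose deconvolved expression is compared.
#' @param probesets Probesets to report (default: all shared).
#' @param alpha Significance cutoff (default 0.05).
#' @return A list of class `paired_report`: `classification` (data
#'   frame), `plot_data` (named list per probeset: `samples` data frame
#'   with expression, reference value, group; `slopes` control/disease).
#' @export
paired_report <- function(psea_results, standard_results, dataset, refs,
                          cell_type, probesets = NULL, alpha = 0.05) {
  psea <- psea_results[psea_results$cell_type == cell_type, ]
  shared <- intersect(psea$probeset_id, standard_results$probeset_id)
  if (!is.null(probesets)) shared <- intersect(shared, probesets)
  if (!length(shared)) stop("no shared probesets to report")
  std <- standard_results[match(shared, standard_results$probeset_id), ]
  pse <- psea[match(shared, psea$probeset_id), ]

  psea_sig <- !is.na(pse$aux_pvalue) & pse$aux_pvalue < alpha
  std_sig <- !is.na(std$fdr) & std$fdr < alpha
  psea_dir <- sign(pse$aux_coef)
  std_dir <- sign(std$log2_fold_change)
  cls <- ifelse(psea_sig & std_sig & psea_dir == std_dir, "concordant",
         ifelse(psea_sig & std_sig, "sign_discordant",
         ifelse(psea_sig, "psea_only",
         ifelse(std_sig, "standard_only", "neither"))))
  classification <- data.frame(
    probeset_id = shared, gene = gene_of(dataset, shared),
    cell_type = cell_type, psea_pvalue = pse$aux_pvalue,
    psea_log2_fc = pse$log2_fold_change,
    standard_fdr = std$fdr, standard_log2_fc = std$log2_fold_change,
    class = cls, stringsAsFactors = FALSE)

  groups <- dataset$groups
  plot_data <- lapply(stats::setNames(shared, shared), function(ps) {
    samples <- data.frame(sample_id = colnames(dataset$matrix),
                          expression = dataset$matrix[ps, ],
                          reference = refs[, cell_type],
                          group = as.character(groups),
                          stringsAsFactors = FALSE)
    slope <- function(sel) {
      if (sum(sel) < 3) return(NA_real_)
      stats::coef(stats::lm(expression ~ reference,
                            data = samples[sel, ]))[["reference"]]
    }
    list(samples = samples,
         slopes = c(control = slope(samples$group == "control"),
                    disease = slope(samples$group == "disease")))
  })
  structure(list(classification = classification, plot_data = plot_data,
                 cell_type = cell_type, alpha = alpha),
            class = "paired_report")
}

#' Plot one probeset of a paired report
#'
#' Draws the two-panel figure for a probeset: left, expression against
#' the cell type's reference signal with separate control and disease
#' regression lines (the slope difference is the cell-type-specific
#' differential expression); right, box plots of the bulk expression
#' values by group (what a standard analysis sees).
#'
#' @param report A [paired_report()].
#' @param probeset_id Probeset to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the probeset's plot data.
#' @export
plot_paired <- function(report, probeset_id, ...) {
  pd <- report$plot_data[[probeset_id]]
  if (is.null(pd)) stop("probeset not in report: ", probeset_id)
  s <- pd$samples
  cols <- ifelse(s$group == "disease", "red", "black")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(s$reference, s$expression, col = cols, pch = 16,
                 xlab = paste(report$cell_type, "reference signal"),
                 ylab = "expression", main = probeset_id, ...)
  for (grp in c("control", "disease")) {
    sel <- s$group == grp
    if (sum(sel) >= 3)
      graphics::abline(stats::lm(expression ~ reference, data = s[sel, ]),
                       col = if (grp == "disease") "red" else "black")
  }
  graphics::boxplot(expression ~ group, data = s,
                    col = c("grey80", "mistyrose"),
                    ylab = "expression", main = probeset_id)
  invisible(pd)
}
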