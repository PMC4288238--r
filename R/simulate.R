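#' Configuration for the synthetic mixed-tissue generator
#'
#' Defines a simulated case/control brain-tissue experiment under the
#' linear mixing model the deconvolution assumes: the bulk expression of
#' gene g in sample s is \eqn{\sum_k a_{sk} x_{gk}} where \eqn{a_{sk}} is
#' the latent abundance of cell type k in sample s and \eqn{x_{gk}} the
#' cell-type-specific expression of g in k, plus additive Gaussian noise.
#' Disease samples differ in two independent ways: their cell-type
#' abundances are shifted multiplicatively (neuronal loss, gliosis), and
#' selected genes have their cell-type-specific expression scaled by a fold
#' change (true differential expression). The first is the composition
#' confound; the second is what the auxiliary-regressor test estimates.
#'
#' Defaults emulate a cortical case/control microarray study: 16 control
#' and 18 disease samples, four cell populations with neurons most
#' abundant, a disease composition shift of 0.65x neurons / 1.3x astrocytes
#' / 1.4x microglia, per-sample abundance coefficient of variation 0.3, and
#' 2000 probesets with linear-scale intensities in 50--500 units.
#'
#' @param n_control,n_disease Sample counts per group.
#' @param cell_types Ordered cell type names (at most 4).
#' @param abundance_means_control Named positive means of per-sample
#'   abundances in controls, one per cell type.
#' @param abundance_shift_disease Named multiplicative factors applied to
#'   the abundance means in disease samples (neuron < 1, glia >= 1 for a
#'   neurodegeneration-like shift).
#' @param abundance_cv Coefficient of variation of per-sample abundances
#'   (Gamma-distributed, so strictly positive).
#' @param n_genes Number of simulated genes (one probeset each), including
#'   markers.
#' @param n_markers_per_type Marker probesets per cell type; markers are
#'   expressed in exactly one cell type and never receive disease effects.
#' @param expression_level_range Range of cell-type-specific base
#'   expression levels (linear units).
#' @param support_probs Probabilities that a non-marker gene is expressed
#'   in 1, 2, 3 or 4 cell types.
#' @param effect_table Data frame of planted disease effects with columns
#'   `gene`, `cell_type`, `fold` (fold > 0). `gene` may be `NA`, in which
#'   case an eligible non-marker gene expressed in that cell type is drawn
#'   at random.
#' @param noise_sd_fraction Additive Gaussian noise standard deviation as a
#'   fraction of the noise-free signal of each observation; values are
#'   truncated at zero.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce identical datasets.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_control = 16, n_disease = 18,
                              cell_types = c("neuron", "astrocyte",
                                             "oligodendrocyte", "microglia"),
                              abundance_means_control = c(
                                neuron = 1.0, astrocyte = 0.6,
                                oligodendrocyte = 0.8, microglia = 0.3),
                              abundance_shift_disease = c(
                                neuron = 0.65, astrocyte = 1.3,
                                oligodendrocyte = 1.0, microglia = 1.4),
                              abundance_cv = 0.3,
                              n_genes = 2000, n_markers_per_type = 5,
                              expression_level_range = c(50, 500),
                              support_probs = c(0.45, 0.25, 0.2, 0.1),
                              effect_table = NULL,
                              noise_sd_fraction = 0.05, seed = 1) {
  if (n_control < 1 || n_disease < 1)
    stop("sample counts must be positive")
  if (length(cell_types) < 1 || length(cell_types) > 4)
    stop("between 1 and 4 cell types are supported")
  if (anyDuplicated(cell_types)) stop("duplicated cell type names")
  k <- length(cell_types)
  abundance_means_control <- rep_len(abundance_means_control, k)
  abundance_shift_disease <- rep_len(abundance_shift_disease, k)
  names(abundance_means_control) <- cell_types
  names(abundance_shift_disease) <- cell_types
  if (any(abundance_means_control <= 0) || any(abundance_shift_disease <= 0))
    stop("abundance means and disease shifts must be strictly positive")
  if (abundance_cv < 0) stop("abundance_cv must be non-negative")
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_markers_per_type < 1) stop("n_markers_per_type must be positive")
  if (n_markers_per_type * k >= n_genes)
    stop("n_genes must exceed the total number of marker genes")
  if (length(expression_level_range) != 2 ||
      any(expression_level_range <= 0) ||
      diff(expression_level_range) < 0)
    stop("expression_level_range must be a positive increasing interval")
  support_probs <- rep_len(support_probs, k)
  support_probs <- support_probs / sum(support_probs)
  if (!is.null(effect_table)) {
    effect_table <- as.data.frame(effect_table, stringsAsFactors = FALSE)
    if (!all(c("cell_type", "fold") %in% names(effect_table)))
      stop("effect_table needs columns cell_type and fold (gene optional)")
    if (is.null(effect_table$gene)) effect_table$gene <- NA_character_
    if (any(effect_table$fold <= 0)) stop("effect fold changes must be > 0")
    if (!all(effect_table$cell_type %in% cell_types))
      stop("effect_table references unknown cell types")
  }
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be non-negative")
  structure(list(
    n_control = n_control, n_disease = n_disease, cell_types = cell_types,
    abundance_means_control = abundance_means_control,
    abundance_shift_disease = abundance_shift_disease,
    abundance_cv = abundance_cv, n_genes = n_genes,
    n_markers_per_type = n_markers_per_type,
    expression_level_range = expression_level_range,
    support_probs = support_probs, effect_table = effect_table,
    noise_sd_fraction = noise_sd_fraction, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Gamma draw with given mean and CV; cv = 0 degenerates to the mean.
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Simulate a heterogeneous-tissue expression dataset
#'
#' Generates an [expression_dataset()] under the linear mixing model of
#' [simulation_config()], together with the ground truth needed to verify
#' every downstream stage: latent per-sample cell-type abundances, the
#' gene-by-cell-type base expression matrix, the marker set, and the
#' realized disease effects.
#'
#' Per-sample abundances are drawn from Gamma distributions with the
#' configured means (shifted in disease) and CV. Marker genes are expressed
#' in exactly one cell type; other genes are expressed in 1--4 cell types
#' with configurable support-size probabilities. Disease effects multiply
#' the cell-type-specific expression of the targeted gene in disease
#' samples only, which is exactly the slope change the auxiliary regressor
#' models.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (an [expression_dataset()]),
#'   `markers` (a [marker_set()]), and `truth` (list: `abundances` sample x
#'   cell type, `base_expression` gene x cell type, `support` logical gene x
#'   cell type, `applied_effects` data frame, `config`).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 200, seed = 42))
#' sim$dataset
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k <- length(config$cell_types)
  n <- config$n_control + config$n_disease
  sample_ids <- sprintf("S%03d", seq_len(n))
  groups <- stats::setNames(
    rep(c("control", "disease"), c(config$n_control, config$n_disease)),
    sample_ids)

  # latent abundances: Gamma per sample, disease means shifted
  means <- matrix(rep(config$abundance_means_control, each = n),
                  nrow = n, dimnames = list(sample_ids, config$cell_types))
  dis <- groups == "disease"
  means[dis, ] <- sweep(means[dis, , drop = FALSE], 2,
                        config$abundance_shift_disease, `*`)
  abundances <- matrix(0, n, k, dimnames = dimnames(means))
  for (j in seq_len(k))
    abundances[, j] <- rgamma_mean_cv(n, 1, config$abundance_cv) * means[, j]

  # gene identities: markers first, then free genes
  n_mark <- config$n_markers_per_type * k
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  probeset_ids <- paste0(gene_ids, "_at")
  marker_type <- rep(config$cell_types, each = config$n_markers_per_type)

  support <- matrix(FALSE, config$n_genes, k,
                    dimnames = list(gene_ids, config$cell_types))
  for (i in seq_len(n_mark)) support[i, marker_type[i]] <- TRUE
  for (i in seq.int(n_mark + 1, config$n_genes)) {
    size <- sample.int(k, 1, prob = config$support_probs)
    support[i, sample.int(k, size)] <- TRUE
  }

  lo <- config$expression_level_range[1]
  hi <- config$expression_level_range[2]
  base_expression <- matrix(0, config$n_genes, k,
                            dimnames = dimnames(support))
  base_expression[support] <- stats::runif(sum(support), lo, hi)

  # disease effects: resolve NA genes to eligible non-marker genes
  applied <- data.frame(gene = character(0), cell_type = character(0),
                        fold = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(config$effect_table) && nrow(config$effect_table)) {
    et <- config$effect_table
    taken <- character(0)
    for (r in seq_len(nrow(et))) {
      ct <- et$cell_type[r]
      g <- et$gene[r]
      if (is.na(g)) {
        eligible <- gene_ids[support[, ct] &
                               seq_len(config$n_genes) > n_mark]
        eligible <- setdiff(eligible, taken)
        if (!length(eligible))
          stop("no eligible non-marker gene expressed in ", ct,
               " left for effect_table row ", r)
        g <- sample(eligible, 1)
      } else {
        if (!g %in% gene_ids) stop("effect gene not simulated: ", g)
        if (match(g, gene_ids) <= n_mark)
          stop("effect_table references marker gene ", g,
               "; markers must stay stable")
        if (!support[g, ct])
          stop("effect gene ", g, " is not expressed in ", ct)
      }
      taken <- c(taken, g)
      applied <- rbind(applied, data.frame(gene = g, cell_type = ct,
                                           fold = et$fold[r],
                                           stringsAsFactors = FALSE))
    }
  }

  # disease samples see fold-scaled cell-type expression for effect genes
  x_disease <- base_expression
  if (nrow(applied))
    for (r in seq_len(nrow(applied)))
      x_disease[applied$gene[r], applied$cell_type[r]] <-
        base_expression[applied$gene[r], applied$cell_type[r]] *
        applied$fold[r]

  signal <- matrix(0, config$n_genes, n,
                   dimnames = list(probeset_ids, sample_ids))
  signal[, !dis] <- base_expression %*% t(abundances[!dis, , drop = FALSE])
  signal[, dis] <- x_disease %*% t(abundances[dis, , drop = FALSE])

  expr <- signal
  if (config$noise_sd_fraction > 0) {
    noise <- stats::rnorm(length(signal), 0,
                          config$noise_sd_fraction * as.vector(signal))
    expr <- pmax(signal + noise, 0)
  }

  gene_map <- stats::setNames(gene_ids, probeset_ids)
  dataset <- expression_dataset(expr, groups, gene_map)

  marker_idx <- seq_len(n_mark)
  markers <- marker_set(lapply(
    stats::setNames(config$cell_types, config$cell_types),
    function(ct) {
      i <- marker_idx[marker_type == ct]
      stats::setNames(gene_ids[i], probeset_ids[i])
    }))

  list(dataset = dataset, markers = markers,
       truth = list(abundances = abundances,
                    base_expression = base_expression,
                    support = support, applied_effects = applied,
                    config = config))
}

#' Write a simulated dataset to a directory
#'
#' Writes the expression matrix, sample metadata, annotation, marker list
#' and ground-truth tables as TSV files that round-trip through
#' [read_expression()] and [load_marker_set()].
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "samples.tsv",
                            "annotation.tsv", "markers.tsv",
                            "truth_abundances.tsv",
                            "truth_base_expression.tsv",
                            "truth_effects.tsv"))
  write_expression(sim$dataset, paths[1], paths[2])
  utils::write.table(
    data.frame(probeset_id = names(sim$dataset$gene_map),
               hgnc_symbol = unname(sim$dataset$gene_map)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- unclass(sim$markers)
  utils::write.table(
    data.frame(cell_type = rep(names(mk), lengths(mk)),
               probeset_id = unlist(lapply(mk, names), use.names = FALSE),
               gene_symbol = unlist(mk, use.names = FALSE)),
    paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(sim$truth$abundances),
               sim$truth$abundances, check.names = FALSE),
    paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(sim$truth$base_expression),
               sim$truth$base_expression, check.names = FALSE),
    paths[6], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$applied_effects, paths[7], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
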