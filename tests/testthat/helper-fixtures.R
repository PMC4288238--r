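# Shared fixtures and independent oracles for the test suite.

# Small hand-built dataset: 2 cell types worth of structure, hand-set values.
tiny_dataset <- function() {
  mat <- rbind(
    ps_a = c(1, 2, 3, 4),
    ps_b = c(2, 4, 6, 8),
    ps_c = c(10, 10, 10, 10)
  )
  colnames(mat) <- paste0("S", 1:4)
  expression_dataset(mat, c(S1 = "control", S2 = "control",
                            S3 = "disease", S4 = "disease"),
                     gene_map = c(ps_a = "GA", ps_b = "GA", ps_c = "GC"))
}

# Default-condition simulation, optionally with planted effects.
quick_sim <- function(n_genes = 300, noise = 0.05, seed = 1, ...) {
  simulate_dataset(simulation_config(n_genes = n_genes,
                                     noise_sd_fraction = noise,
                                     seed = seed, ...))
}

# Two-stage fixture: plant `n_eff` effects on genes expressed exclusively
# in `cell_type`, holding the rest of the simulation fixed (same seed).
sim_with_exclusive_effects <- function(cell_type = "neuron", fold = 0.5,
                                       n_eff = 10, n_genes = 500,
                                       noise = 0.05, seed = 1, ...) {
  cfg0 <- simulation_config(n_genes = n_genes, noise_sd_fraction = noise,
                            seed = seed, ...)
  sim0 <- simulate_dataset(cfg0)
  sup <- sim0$truth$support
  elig <- rownames(sup)[sup[, cell_type] & rowSums(sup) == 1]
  elig <- setdiff(elig, unname(unlist(sim0$markers)))
  genes <- utils::head(elig, n_eff)
  stopifnot(length(genes) == n_eff)
  cfg <- simulation_config(n_genes = n_genes, noise_sd_fraction = noise,
                           seed = seed,
                           effect_table = data.frame(gene = genes,
                                                     cell_type = cell_type,
                                                     fold = fold), ...)
  out <- simulate_dataset(cfg)
  out$effect_genes <- genes
  out
}

# Nigra/putamen-like fixture: astrocyte and oligodendrocyte marker
# probesets replaced by sample-permuted copies of themselves, destroying
# their within-type correlation while keeping marginal intensities.
make_nigra_like <- function(seed = 4, n_genes = 400, noise = 0.05,
                            n_eff = 5, fold = 0.5) {
  sim <- sim_with_exclusive_effects("neuron", fold = fold, n_eff = n_eff,
                                    n_genes = n_genes, noise = noise,
                                    seed = seed)
  mk <- unclass(sim$markers)
  mat <- sim$dataset$matrix
  set.seed(seed + 1000)
  for (ps in c(names(mk$astrocyte), names(mk$oligodendrocyte)))
    mat[ps, ] <- mat[ps, sample(ncol(mat))]
  sim$dataset <- expression_dataset(mat, sim$dataset$groups,
                                    sim$dataset$gene_map)
  sim
}

# Independent brute-force AIC model-selection oracle built on stats::lm,
# enumerating the same candidate order (size, then fixed cell-type order).
oracle_select <- function(y, refs, usable = colnames(refs)) {
  subsets <- list()
  for (size in seq_along(usable))
    subsets <- c(subsets, utils::combn(usable, size, simplify = FALSE))
  best <- NULL
  best_aic <- Inf
  n <- length(y)
  for (s in subsets) {
    df <- data.frame(y = y, refs[, s, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    if (any(is.na(stats::coef(fit)))) next
    rss <- sum(stats::resid(fit)^2)
    aic <- n * log(rss / n) + 2 * (length(s) + 2)
    if (aic < best_aic - 1e-8) {
      best <- s
      best_aic <- aic
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up for small p-value vectors.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
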