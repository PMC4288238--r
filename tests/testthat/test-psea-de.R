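test_that("auxiliary regressor carries reference values on disease samples", {
  aux <- build_aux_regressor(c(1, 2, 3, 4),
                             c("control", "control", "disease", "disease"))
  expect_equal(unname(aux), c(0, 0, 3, 4))
  expect_null(attr(aux, "degenerate"))

  aux0 <- build_aux_regressor(1:4, rep("control", 4))
  expect_equal(as.vector(aux0), rep(0, 4))
  expect_match(attr(aux0, "degenerate"), "controls")

  aux1 <- build_aux_regressor(1:4, rep("disease", 4))
  expect_match(attr(aux1, "degenerate"), "collinear")
})

test_that("a zero-noise halving of neuron expression decomposes exactly", {
  sim <- sim_with_exclusive_effects("neuron", fold = 0.5, n_eff = 2,
                                    n_genes = 120, noise = 0, seed = 16)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  g <- sim$effect_genes[1]
  ps <- paste0(g, "_at")
  y <- sim$dataset$matrix[ps, ]
  m <- select_model_aic(y, refs, usable = "neuron", probeset_id = ps)
  r <- test_differential(m, "neuron", y, refs, sim$dataset$groups)
  expect_equal(r$aux_coef, -0.5 * r$control_coef, tolerance = 1e-8)
  expect_equal(r$log2_fold_change, -1, tolerance = 1e-8)
})

test_that("the joint interaction fit decomposes into per-group slopes", {
  # exact at zero noise, where no common-intercept compromise is needed
  sim <- sim_with_exclusive_effects("neuron", fold = 0.7, n_eff = 2,
                                    n_genes = 120, noise = 0, seed = 17)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  groups <- sim$dataset$groups
  ps <- paste0(sim$effect_genes[1], "_at")
  y <- sim$dataset$matrix[ps, ]
  m <- select_model_aic(y, refs, usable = "neuron", probeset_id = ps)
  r <- test_differential(m, "neuron", y, refs, groups)

  con <- groups == "control"
  slope_c <- coef(lm(y[con] ~ refs[con, "neuron"]))[[2]]
  slope_d <- coef(lm(y[!con] ~ refs[!con, "neuron"]))[[2]]
  expect_equal(r$control_coef, slope_c, tolerance = 1e-8)
  expect_equal(r$control_coef + r$aux_coef, slope_d, tolerance = 1e-8)
})

test_that("the aux test is invariant to rescaling the reference signal", {
  sim <- quick_sim(n_genes = 60, noise = 0.1, seed = 18)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  groups <- sim$dataset$groups
  ps <- setdiff(rownames(sim$dataset$matrix),
                unlist(lapply(unclass(sim$markers), names)))[1]
  y <- sim$dataset$matrix[ps, ]
  m <- select_model_aic(y, refs, probeset_id = ps)
  ct <- m$regressors[1]
  r1 <- test_differential(m, ct, y, refs, groups)

  refs2 <- unclass(refs)
  refs2[, ct] <- refs2[, ct] * 5
  r2 <- test_differential(m, ct, y, refs2, groups)
  expect_equal(r2$aux_pvalue, r1$aux_pvalue, tolerance = 1e-9)
  expect_equal(r2$aux_coef, r1$aux_coef / 5, tolerance = 1e-9)
  expect_equal(r2$log2_fold_change, r1$log2_fold_change, tolerance = 1e-9)
})

test_that("the aux t-test is calibrated under a correctly specified null", {
  # fixed design, iid Gaussian noise, known support: p-values are uniform
  sim <- quick_sim(n_genes = 60, noise = 0.05, seed = 19)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  groups <- sim$dataset$groups
  set.seed(19)
  hits <- 0
  nrep <- 1500
  for (i in seq_len(nrep)) {
    y <- 30 + 1.5 * refs[, "neuron"] + 0.8 * refs[, "microglia"] +
      rnorm(nrow(refs), 0, 25)
    X <- refs[, c("neuron", "microglia")]
    fit <- fit_ols(y, cbind(X, aux = build_aux_regressor(refs[, "neuron"],
                                                         groups)))
    hits <- hits + (fit$coef_pvalues[["aux"]] < 0.05)
  }
  half <- 2.576 * sqrt(0.05 * 0.95 / nrep)
  expect_gt(hits / nrep, 0.05 - half)
  expect_lt(hits / nrep, 0.05 + half)
})

test_that("planted effects are detected with calibrated fold changes", {
  sim <- sim_with_exclusive_effects("neuron", fold = 0.5, n_eff = 10,
                                    n_genes = 500, noise = 0.05, seed = 1)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers,
                                           keep_failing = TRUE))
  de <- attr(suppressMessages(run_psea_de(mods, sim$dataset, refs)),
             "all_tests")
  de <- de[de$gene %in% sim$effect_genes & de$cell_type == "neuron", ]
  expect_equal(nrow(de), 10)
  detected <- de$aux_pvalue < 0.05 & de$aux_coef < 0
  expect_gte(sum(detected), 9)
  expect_lt(abs(mean(de$log2_fold_change[detected]) + 1), 0.15)
})

test_that("effects in one cell type do not leak into another's test", {
  # astrocyte-only effects; neuron tests on other genes stay null-like
  sim <- sim_with_exclusive_effects("astrocyte", fold = 0.5, n_eff = 10,
                                    n_genes = 400, noise = 0.1, seed = 20)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers))
  de <- attr(suppressMessages(run_psea_de(mods, sim$dataset, refs)),
             "all_tests")
  neuron_null <- de[de$cell_type == "neuron" &
                      !(de$gene %in% sim$effect_genes) &
                      !de$untestable & !is.na(de$aux_pvalue), ]
  expect_gt(nrow(neuron_null), 50)
  expect_lt(mean(neuron_null$aux_pvalue < 0.05), 0.12)
})

test_that("DE tables are sorted, filtered at alpha and carry BH FDR", {
  sim <- sim_with_exclusive_effects("neuron", fold = 0.5, n_eff = 5,
                                    n_genes = 250, noise = 0.1, seed = 21)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers))
  de <- suppressMessages(run_psea_de(mods, sim$dataset, refs))
  expect_true(all(diff(de$aux_pvalue) >= 0))
  expect_true(all(de$aux_pvalue < 0.05))
  all_tests <- attr(de, "all_tests")
  ok <- !is.na(all_tests$aux_pvalue)
  expect_true(all(all_tests$fdr[ok] >= all_tests$aux_pvalue[ok]))
  expect_equal(all_tests$fdr[ok],
               bh_oracle(all_tests$aux_pvalue[ok]), tolerance = 1e-12)
  # gene summary counts unique symbols per cell type
  gs <- attr(de, "gene_summary")
  for (ct in names(gs))
    expect_equal(unname(gs[ct]),
                 length(unique(de$gene[de$cell_type == ct & !is.na(de$gene)])))
})
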