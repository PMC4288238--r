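test_that("identical groups give zero fold change and no significance", {
  set.seed(30)
  # 20 probesets x 10 samples, constant within each probeset
  mat <- matrix(rep(runif(20, 50, 500), times = 10), nrow = 20,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  ds <- expression_dataset(mat, rep(c("control", "disease"), each = 5))
  res <- run_standard_de(ds, moderated = FALSE)
  expect_equal(res$log2_fold_change, rep(0, 20))
  expect_true(all(res$zero_variance))
  expect_true(all(is.na(res$pvalue)))
})

test_that("a planted two-fold shift is detected with logFC near one", {
  set.seed(31)
  n <- 15
  base <- runif(200, 100, 400)
  mat <- matrix(0, 200, 2 * n,
                dimnames = list(paste0("p", 1:200),
                                paste0("s", 1:(2 * n))))
  groups <- rep(c("control", "disease"), each = n)
  for (i in 1:200) {
    mu <- c(rep(base[i], n), rep(base[i] * ifelse(i <= 20, 2, 1), n))
    mat[i, ] <- pmax(mu + rnorm(2 * n, 0, base[i] * 0.08), 0)
  }
  ds <- expression_dataset(mat, groups)
  for (moderated in c(TRUE, FALSE)) {
    res <- run_standard_de(ds, moderated = moderated)
    shifted <- res[1:20, ]
    expect_true(all(abs(shifted$log2_fold_change - 1) < 0.25))
    expect_true(all(shifted$fdr < 0.05))
    expect_lt(mean(res$fdr[21:200] < 0.05), 0.05)
  }
})

test_that("the plain-t path matches t.test and BH matches its oracle", {
  sim <- quick_sim(n_genes = 40, noise = 0.2, seed = 32)
  res <- run_standard_de(sim$dataset, moderated = FALSE)
  ylog <- log2(sim$dataset$matrix + 1)
  g <- sim$dataset$groups
  for (ps in rownames(ylog)[c(25, 30, 35)]) {
    tt <- t.test(ylog[ps, g == "disease"], ylog[ps, g == "control"],
                 var.equal = TRUE)
    row <- res[res$probeset_id == ps, ]
    expect_equal(row$pvalue, tt$p.value, tolerance = 1e-10)
    expect_equal(row$log2_fold_change, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
  expect_equal(res$fdr, bh_oracle(res$pvalue), tolerance = 1e-12)
})

test_that("composition change inflates standard DE but not the aux test", {
  cfg <- simulation_config(
    n_genes = 400, noise_sd_fraction = 0.1, seed = 33,
    abundance_shift_disease = c(neuron = 0.6, astrocyte = 1,
                                oligodendrocyte = 1, microglia = 1))
  sim <- simulate_dataset(cfg)
  neuron_genes <- setdiff(
    rownames(sim$truth$support)[sim$truth$support[, "neuron"]],
    unname(unlist(sim$markers)))
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers))
  de <- attr(suppressMessages(run_psea_de(mods, sim$dataset, refs)),
             "all_tests")
  de <- de[de$cell_type == "neuron" & de$gene %in% neuron_genes &
             !de$untestable & !is.na(de$aux_pvalue), ]
  psea_rate <- mean(de$aux_pvalue < 0.05)
  std <- run_standard_de(sim$dataset)
  std_rate <- mean(std$pvalue[std$gene %in% neuron_genes] < 0.05,
                   na.rm = TRUE)
  expect_gt(std_rate - psea_rate, 0.2)
  expect_lt(psea_rate, 0.12)
})

test_that("paired reports classify composition-only and true effects", {
  # strong neuron loss AND one gene truly up-regulated in neurons: bulk
  # falls although per-cell expression rises
  cfg0 <- simulation_config(
    n_genes = 300, noise_sd_fraction = 0.05, seed = 34,
    abundance_shift_disease = c(neuron = 0.4, astrocyte = 1,
                                oligodendrocyte = 1, microglia = 1))
  sim0 <- simulate_dataset(cfg0)
  sup <- sim0$truth$support
  excl <- setdiff(rownames(sup)[sup[, "neuron"] & rowSums(sup) == 1],
                  unname(unlist(sim0$markers)))
  up_gene <- excl[1]     # expression rises but abundance falls more
  flat_gene <- excl[2]   # composition change only
  sim <- simulate_dataset(simulation_config(
    n_genes = 300, noise_sd_fraction = 0.05, seed = 34,
    abundance_shift_disease = c(neuron = 0.4, astrocyte = 1,
                                oligodendrocyte = 1, microglia = 1),
    effect_table = data.frame(gene = up_gene, cell_type = "neuron",
                              fold = 1.8)))
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers,
                                           keep_failing = TRUE))
  de_all <- attr(suppressMessages(run_psea_de(mods, sim$dataset, refs)),
                 "all_tests")
  std <- run_standard_de(sim$dataset)
  rep <- paired_report(de_all, std, sim$dataset, refs, "neuron",
                       probesets = paste0(c(up_gene, flat_gene), "_at"))
  cls <- rep$classification
  expect_equal(cls$class[cls$gene == flat_gene], "standard_only")
  expect_equal(cls$class[cls$gene == up_gene], "sign_discordant")
  expect_gt(cls$psea_log2_fc[cls$gene == up_gene], 0)
  expect_lt(cls$standard_log2_fc[cls$gene == up_gene], 0)
  # regression slopes: disease slope above control for the true effect
  sl <- rep$plot_data[[paste0(up_gene, "_at")]]$slopes
  expect_gt(sl[["disease"]], sl[["control"]])
})
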