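ref_fixture <- function(seed = 3, n_genes = 60, noise = 0) {
  sim <- quick_sim(n_genes = n_genes, noise = noise, seed = seed)
  list(sim = sim,
       refs = build_reference_signals(sim$dataset, sim$markers))
}

test_that("exact single-regressor relations are fitted exactly", {
  fx <- ref_fixture()
  refs <- fx$refs
  y <- 2 * refs[, "neuron"]
  fit <- fit_ols(y, refs[, "neuron", drop = FALSE])
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  m <- select_model_aic(y, refs)
  expect_equal(m$regressors, "neuron")

  y2 <- refs[, "astrocyte"] + refs[, "microglia"]
  m2 <- select_model_aic(y2, refs)
  expect_setequal(m2$regressors, c("astrocyte", "microglia"))
})

test_that("a constant response is skipped with a recorded reason", {
  fx <- ref_fixture()
  m <- select_model_aic(rep(100, nrow(fx$refs)), fx$refs)
  expect_s3_class(m, "psea_skip")
  expect_match(m$reason, "zero-variance")
})

test_that("flat noise yields a non-significant regression", {
  fx <- ref_fixture()
  set.seed(1)
  y <- 100 + rnorm(nrow(fx$refs), 0, 1e-3)
  fit <- fit_ols(y, fx$refs[, "neuron", drop = FALSE])
  expect_lt(abs(unname(fit$coefficients)), 1e-3)
  expect_gt(fit$f_pvalue, 0.05)
})

test_that("fit_ols matches the normal-equation solution and recovers truth", {
  fx <- ref_fixture(seed = 7)
  refs <- fx$refs
  set.seed(7)
  y <- 1.5 * refs[, "astrocyte"] + 0.5 * refs[, "oligodendrocyte"] +
    rnorm(nrow(refs), 0, 5)
  X <- refs[, c("astrocyte", "oligodendrocyte")]
  fit <- fit_ols(y, X)
  # independent closed-form OLS via the normal equations
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(drop(beta)), tolerance = 1e-10)
  expect_lt(abs(fit$coefficients[["astrocyte"]] - 1.5),
            3 * fit$coef_se[["astrocyte"]])
  expect_lt(abs(fit$coefficients[["oligodendrocyte"]] - 0.5),
            3 * fit$coef_se[["oligodendrocyte"]])
})

test_that("rank-deficient designs are marked unfittable", {
  fx <- ref_fixture()
  X <- cbind(a = fx$refs[, "neuron"], b = fx$refs[, "neuron"])
  fit <- fit_ols(fx$refs[, "astrocyte"], X)
  expect_false(fit$ok)
})

test_that("AIC selection equals the brute-force enumeration oracle", {
  for (seed in 1:3) {
    sim <- quick_sim(n_genes = 60, noise = 0.1, seed = seed)
    refs <- build_reference_signals(sim$dataset, sim$markers)
    ps <- setdiff(rownames(sim$dataset$matrix),
                  unlist(lapply(unclass(sim$markers), names)))
    for (p in ps[seq(1, length(ps), by = 2)]) {
      y <- sim$dataset$matrix[p, ]
      m <- select_model_aic(y, refs)
      expect_equal(sort(m$regressors), sort(oracle_select(y, unclass(refs))),
                   info = paste(seed, p))
    }
  }
})

test_that("zero-noise selection recovers the true support with exact coefficients", {
  sim <- quick_sim(n_genes = 120, noise = 0, seed = 13)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers))
  expect_equal(mods$counts[["passing"]], mods$counts[["fitted"]])
  amean <- colMeans(sim$truth$abundances)
  for (m in mods$models) {
    g <- sim$dataset$gene_map[[m$probeset_id]]
    truth <- colnames(sim$truth$support)[sim$truth$support[g, ]]
    expect_setequal(m$regressors, truth)
    expected <- sim$truth$base_expression[g, m$regressors] *
      amean[m$regressors] / 100
    expect_equal(unname(m$coefficients), unname(expected),
                 tolerance = 1e-8)
  }
})

test_that("quality filters implement the published thresholds", {
  fx <- ref_fixture(seed = 9)
  refs <- fx$refs
  set.seed(9)
  y <- 2 * refs[, "neuron"] + rnorm(nrow(refs), 0, 10)
  m <- select_model_aic(y, refs)

  m1 <- m; m1$adj_r2 <- 0.59
  expect_false(apply_quality_filters(m1)$pass_flags[["adj_r2"]])
  m1$adj_r2 <- 0.61
  expect_true(apply_quality_filters(m1)$pass_flags[["adj_r2"]])

  m2 <- m; m2$mean_expression <- 100; m2$intercept <- 60
  expect_false(apply_quality_filters(m2)$pass_flags[["intercept"]])
  m2$intercept <- -49
  expect_true(apply_quality_filters(m2)$pass_flags[["intercept"]])

  m3 <- m; m3$coefficients <- c(neuron = 2, astrocyte = -0.01)
  expect_false(apply_quality_filters(m3)$pass_flags[["coef_sign"]])

  m4 <- m; m4$f_pvalue <- 0.06
  expect_false(apply_quality_filters(m4)$pass_flags[["f_test"]])
  m5 <- m; m5$shapiro_pvalue <- 0.005
  expect_false(apply_quality_filters(m5)$pass_flags[["shapiro"]])
})

test_that("relaxing any threshold never removes a passing model", {
  fx <- ref_fixture(seed = 21)
  refs <- fx$refs
  strict <- psea_filters()
  loose <- psea_filters(f_alpha = 0.2, min_adj_r2 = 0.3,
                        shapiro_alpha = 0.001, max_intercept_frac = 1)
  set.seed(21)
  for (i in 1:40) {
    y <- pmax(runif(1, 0, 2) * refs[, sample(4, 1)] +
                rnorm(nrow(refs), 0, runif(1, 1, 60)), 0)
    m <- select_model_aic(y, refs)
    if (is.null(m)) next
    if (apply_quality_filters(m, strict)$overall_pass)
      expect_true(apply_quality_filters(m, loose)$overall_pass)
  }
})

test_that("marker probesets are removed from the model tables", {
  sim <- quick_sim(n_genes = 40, noise = 0, seed = 14)
  refs <- build_reference_signals(sim$dataset, sim$markers)
  marker_ps <- unlist(lapply(unclass(sim$markers), names),
                      use.names = FALSE)
  only_markers <- expression_dataset(
    sim$dataset$matrix[marker_ps, ], sim$dataset$groups,
    sim$dataset$gene_map)
  mods <- suppressMessages(run_psea_models(only_markers, refs, sim$markers))
  expect_length(mods$models, 0)
})

test_that("the passing fraction degrades with noise", {
  rate <- sapply(c(0.05, 0.5), function(nf) {
    sim <- quick_sim(n_genes = 150, noise = nf, seed = 15)
    refs <- build_reference_signals(sim$dataset, sim$markers)
    mods <- suppressMessages(run_psea_models(sim$dataset, refs, sim$markers))
    mods$counts[["passing"]] / mods$counts[["fitted"]]
  })
  expect_gt(rate[1], rate[2])
})
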