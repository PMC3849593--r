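test_that("the sparse-regression generator honours its stated design", {
  dat <- generate_table1_data(seed = 81)
  expect_identical(dim(dat$train$X), c(100L, 90L))
  expect_identical(dim(dat$test$X), c(400L, 90L))
  expect_identical(sum(dat$beta_true == 0), 30L)
  expect_identical(dat$groups, rep(1:3, each = 30))
  expect_identical(length(dat$zero_idx), 30L)

  dat2 <- generate_table1_data(seed = 81)
  expect_identical(dat2$train$X, dat$train$X)
  expect_identical(dat2$beta_true, dat$beta_true)
})

test_that("nonzero coefficients follow the Laplace(0, 1/7) law", {
  set.seed(82)
  nz <- unlist(lapply(1:50, function(i) {
    b <- generate_table1_data()$beta_true
    b[b != 0]
  }))
  expect_identical(length(nz), 3000L)
  expect_lt(abs(var(nz) - 2 / 49), 4 * sqrt(5 * (2 / 49)^2 / 3000))
  expect_lt(abs(mean(nz)), 4 * sqrt(2 / 49 / 3000))
  # direct check of the Laplace sampler itself
  x <- rlaplace(200000, 0, 1 / 7)
  expect_lt(abs(var(x) - 2 / 49), 3e-3)
  expect_lt(abs(mean(abs(x)) - 1 / 7), 2e-3)
})

test_that("the GBM-like generator reproduces the cohort shape", {
  sim <- generate_omics_data(seed = 83)
  d <- sim$dataset
  expect_identical(dim(d$mrna), c(163L, 49L))
  expect_identical(length(d$survival_days), 163L)
  expect_true(all(d$survival_days > 0))
  expect_identical(ncol(d$meth), as.integer(sum(sim$meth_counts)))
  expect_identical(ncol(d$cn), as.integer(sum(sim$cn_counts)))
  expect_true(all(sim$meth_counts %in% 0:21))
  expect_identical(sum(sim$meth_counts == 0), 1L)  # one gene lacks methylation
  expect_true(all(sim$cn_counts >= 1 & sim$cn_counts <= 43))
  expect_true(ncol(d$meth) >= 48 && ncol(d$meth) <= 1008)

  # missingness close to the design rates
  expect_lt(abs(mean(is.na(d$meth)) - 0.05), 0.01)
  expect_lt(mean(is.na(d$cn)), 0.004)

  sim2 <- generate_omics_data(seed = 83)
  expect_identical(sim2$dataset$mrna, d$mrna)
  expect_identical(sim2$truth, sim$truth)
})

test_that("generated expression is exactly the sum of its components", {
  sim <- generate_omics_data(omics_design(n_samples = 30, n_genes = 5,
                                          meth_range = c(1, 3),
                                          cn_range = c(1, 4),
                                          missing_meth = 0, missing_cn = 0),
                             seed = 84)
  total <- sim$components$M + sim$components$CN + sim$components$O
  expect_equal(unname(sim$dataset$mrna), unname(total), tolerance = 1e-14)
})

test_that("planted truth respects eligibility and sizes", {
  sim <- generate_omics_data(seed = 85)
  truth <- sim$truth
  hits <- truth[truth$beta != 0, ]
  expect_identical(nrow(hits), 6L)
  expect_true(all(abs(hits$beta) == 0.5))
  expect_setequal(unique(sign(hits$beta)), c(1, -1))
  # no effect planted on the M slot of the methylation-free gene
  no_meth_gene <- colnames(sim$dataset$mrna)[sim$meth_counts == 0]
  expect_false(any(hits$gene_id == no_meth_gene & hits$platform == "M"))
})

test_that("simulation-study driver aggregates replicate metrics", {
  study <- run_simulation_study(
    simulation_design(n_train = 60, n_test = 40, p_per_group = 4,
                      n_zero = 4),
    n_replicates = 2, n_iter = 250, burn_in = 50, seed = 86,
    methods = c("ols", "lasso"))
  expect_identical(sort(unique(study$replicates$replicate)), 1:2)
  expect_true(all(c("sigma2_hat_mean", "mse_ratio_test_mc_se",
                    "n_replicates") %in% names(study$summary)))
  ols <- study$replicates[study$replicates$method == "least squares", ]
  expect_true(all(ols$mse_ratio_train == 1 & ols$mse_ratio_test == 1))
})
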