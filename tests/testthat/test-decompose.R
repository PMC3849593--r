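test_that("pc_scores passes single markers through and collapses rank-1 blocks", {
  set.seed(31)
  v <- matrix(rnorm(20), 20, 1)
  ps <- pc_scores(v)
  expect_identical(ps$k, 1L)
  expect_identical(ps$scores, v)

  two <- cbind(v, 2 * v)  # perfectly correlated
  ps2 <- pc_scores(two)
  expect_identical(ps2$k, 1L)
  expect_equal(ps2$explained[1], 1, tolerance = 1e-12)
})

test_that("component count follows the cumulative-variance rule", {
  eigenvalues <- c(5, 3, 1, 0.5, 0.5)  # cum fractions .5 .8 .9 .95 1
  X <- matrix_with_spectrum(50, eigenvalues)
  # oracle: eigendecomposition of the sample covariance
  ev <- sort(eigen(cov(X))$values, decreasing = TRUE)
  expect_equal(ev, eigenvalues, tolerance = 1e-8)
  ps <- pc_scores(X, variance_threshold = 0.90)
  expect_identical(ps$k, 3L)
  expect_identical(pc_scores(X, variance_threshold = 0.95)$k, 4L)
  expect_identical(pc_scores(X, variance_threshold = 0.5)$k, 1L)
})

test_that("retained score columns are mutually orthogonal", {
  set.seed(32)
  X <- matrix(rnorm(40 * 6), 40, 6)
  ps <- pc_scores(X, variance_threshold = 0.99)
  g <- crossprod(ps$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("zero-variance blocks yield no components, with a warning", {
  X <- matrix(1, 10, 3)
  expect_warning(ps <- pc_scores(X), "zero-variance")
  expect_identical(ps$k, 0L)
  expect_identical(ncol(ps$scores), 0L)
})

test_that("a noiseless linear gene is decomposed exactly", {
  set.seed(33)
  n <- 30
  ms <- matrix(rnorm(n), n, 1)
  cs <- matrix(rnorm(n), n, 1)
  mrna <- drop(2 * ms - 1 * cs) + 3
  d <- decompose_gene(mrna, ms, cs, gene_id = "g")
  expect_equal(d$coef_M, 2, tolerance = 1e-10)
  expect_equal(d$coef_CN, -1, tolerance = 1e-10)
  expect_equal(d$M, drop(2 * ms), tolerance = 1e-10)
  expect_equal(d$CN, drop(-cs), tolerance = 1e-10)
  expect_equal(d$O, rep(3, n), tolerance = 1e-10)
  expect_lt(max(abs(d$M + d$CN + d$O - mrna)), 1e-8)
})

test_that("scores orthogonal to the response give a null fit", {
  n <- 40
  mrna <- rep(c(1, -1), n / 2)
  ms <- matrix(rep(c(1, 1, -1, -1), n / 4), n, 1)  # orthogonal to mrna
  d <- decompose_gene(mrna, ms, NULL)
  expect_equal(d$coef_M, 0, tolerance = 1e-10)
  expect_equal(d$O, mrna, tolerance = 1e-10)
})

test_that("genes without methylation markers get a zero M component", {
  set.seed(34)
  n <- 25
  cs <- matrix(rnorm(2 * n), n, 2)
  mrna <- rnorm(n)
  d <- decompose_gene(mrna, NULL, cs)
  expect_identical(d$K, 0L)
  expect_identical(d$M, rep(0, n))
  expect_lt(max(abs(d$M + d$CN + d$O - mrna)), 1e-8)
})

test_that("the additive identity holds on every synthetic gene", {
  sim <- generate_omics_data(omics_design(n_samples = 40, n_genes = 6,
                                          meth_range = c(1, 4),
                                          cn_range = c(1, 5)), seed = 35)
  decomps <- decompose_dataset(sim$dataset)
  err <- vapply(seq_along(decomps), function(i) {
    d <- decomps[[i]]
    max(abs(d$M + d$CN + d$O - sim$dataset$mrna[, d$gene_id]))
  }, numeric(1))
  expect_lt(max(err), 1e-8)
})

test_that("clinical design stacks, labels and standardizes components", {
  set.seed(36)
  n <- 20
  d1 <- decompose_gene(rnorm(n), matrix(rnorm(n), n, 1),
                       matrix(rnorm(n), n, 1), gene_id = "g1")
  d2 <- decompose_gene(rnorm(n), NULL, matrix(rnorm(n), n, 1),
                       gene_id = "g2")
  surv <- exp(rnorm(n))
  des <- build_clinical_design(list(d1, d2), surv)
  expect_identical(ncol(des$X), 5L)  # M:1, CN:2, O:2
  expect_identical(as.integer(table(des$groups)), c(1L, 2L, 2L))
  expect_lt(max(abs(colMeans(des$X))), 1e-10)
  expect_lt(max(abs(apply(des$X, 2, sd) - 1)), 1e-10)
  expect_equal(des$y, log(surv))
  expect_identical(des$annotation$platform, c("M", "CN", "CN", "O", "O"))
})

test_that("the GBM-shaped generator yields the expected design width", {
  sim <- generate_omics_data(omics_design(), seed = 37)
  decomps <- decompose_dataset(sim$dataset)
  des <- build_clinical_design(decomps)
  # 49 genes, exactly one without methylation: 48 + 49 + 49 columns
  expect_identical(ncol(des$X), 146L)
  expect_identical(as.integer(table(des$groups)), c(48L, 49L, 49L))
})
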