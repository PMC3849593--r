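test_that("effect cutoffs evaluate the log bounds exactly", {
  cuts <- effect_cutoffs(0.05)
  expect_equal(unname(cuts), c(log(0.95), log(1.05)), tolerance = 1e-15)
  expect_equal(unname(cuts["lower"]), -0.05129329, tolerance = 1e-6)
  expect_equal(unname(cuts["upper"]), 0.04879016, tolerance = 1e-6)
  # shrinking delta sends both cutoffs to zero; log concavity skews the region
  small <- effect_cutoffs(1e-8)
  expect_lt(max(abs(small)), 2e-8)
  expect_gt(abs(cuts["lower"]), cuts["upper"])
  expect_error(effect_cutoffs(0), "delta")
  expect_error(effect_cutoffs(1), "delta")
  expect_error(effect_cutoffs(-0.1), "delta")
})

test_that("the four-draw worked example gives p+ = 0.5, p- = 0.25, no flag", {
  ch <- fake_chain(matrix(c(0.10, 0.06, 0.02, -0.10), 4, 1))
  rep <- exceedance_probabilities(ch, delta = 0.05)
  expect_equal(rep$p_plus, 0.5)
  expect_equal(rep$p_minus, 0.25)
  expect_identical(rep$flag, "none")  # strict > 0.5 rule: a tie is not flagged
})

test_that("extreme draws are flagged and flags are mutually exclusive", {
  ch <- fake_chain(cbind(rep(0.2, 10), rep(-0.2, 10), rnorm(10, 0, 1e-4)))
  rep <- exceedance_probabilities(ch, delta = 0.05)
  expect_identical(rep$flag, c("positive", "negative", "none"))
  expect_equal(rep$p_plus[1], 1)
  expect_true(all(rep$p_plus + rep$p_minus <= 1))
})

test_that("exceedance probabilities are monotone non-increasing in delta", {
  set.seed(61)
  ch <- fake_chain(matrix(rnorm(5000, mean = 0.03, sd = 0.05), 1000, 5))
  deltas <- c(0.01, 0.05, 0.10, 0.3)
  reps <- lapply(deltas, function(d) exceedance_probabilities(ch, d))
  for (i in seq_len(length(deltas) - 1)) {
    expect_true(all(reps[[i + 1]]$p_plus <= reps[[i]]$p_plus + 1e-12))
    expect_true(all(reps[[i + 1]]$p_minus <= reps[[i]]$p_minus + 1e-12))
  }
})

test_that("symmetric posteriors are never flagged", {
  set.seed(62)
  ch <- fake_chain(matrix(rnorm(3000, 0, 0.2), 1000, 3))
  rep <- exceedance_probabilities(ch, delta = 0.05)
  expect_true(all(abs(rep$p_plus - rep$p_minus) < 0.1))
  expect_identical(unique(rep$flag), "none")
})

test_that("gene-level aggregation groups flagged platforms per gene", {
  ann <- tibble::tibble(column = c("M:g1", "O:g1", "CN:g2", "O:g3"),
                        gene_id = c("g1", "g1", "g2", "g3"),
                        platform = c("M", "O", "CN", "O"))
  draws <- cbind(rep(0.3, 20), rep(0.25, 20), rep(-0.4, 20), rep(0, 20))
  colnames(draws) <- ann$column
  ch <- fake_chain(draws, annotation = ann)
  rep <- exceedance_probabilities(ch, delta = 0.05)
  gr <- gene_level_report(rep)
  expect_identical(nrow(gr), 2L)
  g1 <- gr[gr$gene_id == "g1", ]
  expect_identical(g1$n_flagged, 2L)
  expect_identical(g1$platforms, "M,O")
  expect_identical(gr$directions[gr$gene_id == "g2"], "negative")

  # no flags -> empty table
  ch0 <- fake_chain(matrix(0, 10, 4, dimnames = list(NULL, ann$column)),
                    annotation = ann)
  expect_identical(nrow(gene_level_report(
    exceedance_probabilities(ch0, 0.05))), 0L)
})

test_that("selection reports render and export", {
  ann <- tibble::tibble(column = c("M:g1", "O:g1"), gene_id = c("g1", "g1"),
                        platform = c("M", "O"))
  draws <- matrix(rnorm(40, 0.2, 0.05), 20, 2,
                  dimnames = list(NULL, ann$column))
  rep <- exceedance_probabilities(fake_chain(draws, ann), 0.05)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(rep, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_identical(nrow(back), 2L)
  expect_equal(back$p_plus, rep$p_plus)
})
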