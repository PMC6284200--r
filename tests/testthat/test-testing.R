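test_that("Wald statistic: hand values, null identity, scale homogeneity", {
  expect_equal(wald_statistic(10, 10, 5, 5), 0)
  expect_equal(wald_pvalue(wald_statistic(10, 10, 5, 5)), 1)
  expect_equal(wald_statistic(10, 20, 10, 20), 10 / sqrt(30))
  w1 <- wald_statistic(10, 20, 10, 20)
  w2 <- wald_statistic(20, 40, 20, 40)
  expect_equal(w2, sqrt(2) * w1)
  expect_equal(wald_statistic(3, 5, 0, 0), Inf)
  expect_equal(wald_statistic(3, 3, 0, 0), 0)
  expect_error(wald_statistic(1, 2, -1, 1), "non-negative")
})

test_that("Wald p-values use the two-sided standard normal", {
  expect_equal(wald_pvalue(0), 1)
  expect_equal(wald_pvalue(1.959964), 0.05, tolerance = 1e-4)
  expect_equal(wald_pvalue(Inf), 0)
  expect_error(wald_pvalue(-1), "non-negative")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("fold change conventions at zero means", {
  expect_equal(fold_change(10, 15), 1.5)
  expect_equal(fold_change(0, 0), 1)
  expect_equal(fold_change(0, 4), Inf)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("DEG calling combines the FDR and fold-change thresholds strictly", {
  expect_true(call_degs(0.01, 1.6))
  expect_false(call_degs(0.001, 1.2))
  expect_false(call_degs(0.06, 0.5))
  expect_true(call_degs(0.01, Inf))
  expect_false(call_degs(0.05, 1.6))  # strict inequality on alpha
  expect_error(call_degs(0.01, 2, alpha = 1.5), "alpha")
})

test_that("the pipeline is deterministic and Mix takes the per-gene minimum p", {
  sim <- simulate_dataset(synth_params(150, seed = 51, mu_range = c(5, 2000)),
                          n_de = 30, seed = 51)
  f1 <- suppressMessages(dpseq(sim$counts, sim$condition, mode = "Mix"))
  f2 <- suppressMessages(dpseq(sim$counts, sim$condition, mode = "Mix"))
  expect_equal(tidy(f1), tidy(f2))

  r <- tidy(f1)
  expect_equal(r$pvalue, pmin(r$pvalue_dp, r$pvalue_nb))
  expect_true(all(r$padj >= r$pvalue))

  fdp <- suppressMessages(dpseq(sim$counts, sim$condition, mode = "DP"))
  expect_equal(tidy(fdp)$pvalue, r$pvalue_dp)

  g <- glance(f1)
  expect_equal(g$n_genes, nrow(r))
  expect_true(all(c("m0_dp", "tau_dp", "m0_nb", "tau_nb") %in% names(g)))
})

test_that("the pipeline rejects invalid designs", {
  m <- pois_counts(30, 5, 20, seed = 52)
  expect_error(dpseq(m, factor(c("a", "a", "a", "a", "b"))), "replicates")
  m6 <- pois_counts(30, 6, 20, seed = 53)
  expect_error(dpseq(m6, factor(rep(c("a", "b", "c"), 2))), "exactly 2 groups")
})

test_that("strong effects are detected with high power in a small dataset", {
  p <- synth_params(200, seed = 54)
  p$mu <- pmax(p$mu, 50)
  sim <- simulate_dataset(p, n_de = 40, fc_log2_range = c(1, 2), seed = 54)
  f <- suppressMessages(dpseq(sim$counts, sim$condition, mode = "DP"))
  r <- tidy(f)
  m <- match(r$gene, sim$truth$gene)
  expect_gt(mean(r$padj[sim$truth$is_de[m]] < 0.05), 0.5)
})

test_that("per-gene results carry dispersion classes and fold changes that match the counts", {
  m <- toy_counts(c(10, 12, 14, 22, 26, 24,
                    5, 5, 6, 5, 6, 5), n_samples = 6)
  m <- rbind(m, matrix(0, 1, 6, dimnames = list("g99", colnames(m))))
  f <- suppressMessages(dpseq(m, two_group(), mode = "DP",
                              normalization = "total"))
  r <- tidy(f)
  expect_equal(nrow(r), 2)       # all-zero gene dropped
  expect_equal(f$n_filtered, 1)
  expect_true(all(r$dispersion_class %in% c("underdispersed", "non-underdispersed")))
})
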