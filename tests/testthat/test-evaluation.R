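toy_truth <- c(TRUE, TRUE, FALSE, FALSE)
toy_p <- c(0.01, 0.2, 0.01, 0.9)

test_that("confusion metrics match hand counts and report empty strata as NA", {
  cm <- confusion_metrics(toy_p, toy_truth, alpha = 0.05)
  expect_equal(cm$tpr, 0.5)
  expect_equal(cm$fpr, 0.5)

  all1 <- confusion_metrics(rep(1, 4), toy_truth)
  expect_equal(all1$fpr, 0)
  expect_equal(all1$tpr, 0)

  onlyde <- confusion_metrics(c(0.01, 0.2), c(TRUE, TRUE))
  expect_true(is.na(onlyde$fpr))
  expect_equal(onlyde$tpr, 0.5)

  strat <- confusion_metrics(toy_p, toy_truth, class = c("u", "u", "n", "n"))
  expect_equal(strat$stratum, c("all", "n", "u"))
  expect_error(confusion_metrics(toy_p, toy_truth[1:3]), "align")
})

test_that("null p-values give a false-positive rate near the significance level", {
  set.seed(61)
  p <- runif(1e4)
  cm <- confusion_metrics(p, rep(c(TRUE, FALSE), 5e3))
  expect_lt(abs(cm$fpr - 0.05), 3 * sqrt(0.05 * 0.95 / 5e3))
})

test_that("ROC/AUC equals the Mann-Whitney oracle and is transform-invariant", {
  # perfect separation
  expect_equal(roc_auc(c(0.01, 0.02, 0.5, 0.9), toy_truth)$auc, 1)

  r <- roc_auc(toy_p, toy_truth)
  expect_equal(r$auc, mw_auc_oracle(toy_p, toy_truth))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)

  set.seed(62)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    p <- round(runif(n), 2)          # force ties
    de <- runif(n) < 0.4
    if (!any(de) || all(de)) next
    expect_equal(roc_auc(p, de)$auc, mw_auc_oracle(p, de))
    expect_equal(roc_auc(p^3, de)$auc, roc_auc(p, de)$auc)  # monotone transform
  }

  set.seed(63)
  p <- runif(2000)
  de <- runif(2000) < 0.5
  expect_lt(abs(roc_auc(p, de)$auc - 0.5), 0.05)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "non-DE")
})

test_that("ROC curves are monotone non-decreasing in both coordinates", {
  set.seed(64)
  p <- round(runif(300), 2)
  de <- runif(300) < 0.3
  cv <- roc_auc(p, de)$curve
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("precision-recall curves match hand enumeration and conventions", {
  pc <- pr_curve(toy_p, toy_truth)$curve
  # thresholds 0.01 (tp 1, fp 1), 0.2 (tp 2, fp 1), 0.9 (tp 2, fp 2)
  expect_equal(pc$recall, c(0, 0.5, 1, 1))
  expect_equal(pc$precision, c(0.5, 0.5, 2 / 3, 0.5))
  expect_true(all(diff(pc$recall) >= 0))

  # perfect classifier: precision stays 1 until recall reaches 1
  perfect <- pr_curve(c(0.01, 0.02, 0.5, 0.9), toy_truth)$curve
  expect_true(all(perfect$precision[1:3] == 1))
  expect_equal(perfect$recall[3], 1)

  allde <- pr_curve(c(0.2, 0.4), c(TRUE, TRUE))$curve
  expect_true(all(allde$precision == 1))
  expect_error(pr_curve(c(0.1, 0.2), c(FALSE, FALSE)), "DE gene")
})

test_that("method comparison is self-consistent and scores missing genes as p = 1", {
  truth <- tibble::tibble(gene = paste0("g", 1:6),
                          is_de = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  tab <- tibble::tibble(gene = truth$gene,
                        pvalue = c(0.001, 0.04, 0.2, 0.01, 0.5, 0.9))
  out <- compare_methods(list(m1 = tab, m2 = tab), truth)
  expect_equal(out$fpr[out$method == "m1"], out$fpr[out$method == "m2"])
  cm <- confusion_metrics(tab$pvalue, truth$is_de)
  expect_equal(out$fpr[out$method == "m1"], cm$fpr)
  expect_equal(out$tpr[out$method == "m1"], cm$tpr)
  expect_equal(out$auc[out$method == "m1"], mw_auc_oracle(tab$pvalue, truth$is_de))

  short <- tab[1:4, ]
  expect_message(out2 <- compare_methods(list(m3 = short), truth), "missing")
  expect_equal(out2$fpr, confusion_metrics(c(tab$pvalue[1:4], 1, 1), truth$is_de)$fpr)

  strat <- compare_methods(
    list(m1 = tab), truth,
    classes = tibble::tibble(gene = truth$gene,
                             dispersion_class = rep(c("underdispersed",
                                                      "non-underdispersed"), 3)))
  expect_setequal(strat$stratum, c("all", "underdispersed", "non-underdispersed"))
  expect_error(compare_methods(list(tab), truth), "named")
})

test_that("feeding the pipeline's own output through the harness reproduces its metrics", {
  sim <- simulate_dataset(synth_params(150, seed = 65, mu_range = c(10, 1000)),
                          n_de = 30, seed = 65)
  f <- suppressMessages(dpseq(sim$counts, sim$condition, mode = "DP"))
  r <- tidy(f)
  out <- compare_methods(list(dp = r[, c("gene", "pvalue", "fc")]), sim$truth)
  cm <- confusion_metrics(r$pvalue, sim$truth$is_de[match(r$gene, sim$truth$gene)])
  expect_equal(out$fpr, cm$fpr)
  expect_equal(out$tpr, cm$tpr)
  expect_equal(out$n_deg, sum(r$deg))
})
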