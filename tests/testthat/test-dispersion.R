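test_that("pooled moments: hand example, zero variance, and depth invariance", {
  m <- toy_counts(c(8, 10, 12, 8, 10, 12))
  mom <- pooled_moments(m, two_group(), rep(1, 6))
  expect_equal(mom$mu, 10)
  expect_equal(mom$sigma2, 4)

  flat <- toy_counts(rep(7, 6))
  mom2 <- pooled_moments(flat, two_group(), rep(1, 6))
  expect_equal(mom2$sigma2, 0)

  # scaling every size factor leaves the dispersion class unchanged
  m3 <- pois_counts(100, 6, 20, seed = 8)
  a <- pooled_moments(m3, two_group(), rep(1, 6))
  b <- pooled_moments(m3, two_group(), rep(3, 6))
  expect_equal(a$sigma2 < a$mu, b$sigma2 < b$mu)
})

test_that("moments initialization follows the NB floor and DP cap rules", {
  expect_equal(initial_dispersion(10, 30, "NB"), 0.2)
  expect_equal(initial_dispersion(10, 30, "DP"), 1 / 3)
  expect_equal(initial_dispersion(10, 5, "NB"), 1e-8)   # underdispersed: floored
  expect_equal(initial_dispersion(10, 5, "DP"), 2)
  expect_equal(initial_dispersion(10, 10, "NB"), 1e-8)  # equidispersed: floored
  expect_equal(initial_dispersion(10, 10, "DP"), 1)
  expect_equal(initial_dispersion(10, 0, "DP"), 1e4)    # zero variance: cap
  expect_error(initial_dispersion(0, 1, "DP"), "positive")
})

test_that("gene-wise MLE hits boundaries and recovers simulated dispersions", {
  # zero variance: the plain DP likelihood increases in theta without bound;
  # the Cox-Reid term caps it at a large finite value
  y <- rep(5, 6)
  expect_equal(genewise_dispersion(y, rep(5, 6), 1, "DP", cr = FALSE), 1e4)
  expect_gt(genewise_dispersion(y, rep(5, 6), 1, "DP"), 10)

  # Poisson data: NB dispersion collapses to the floor region
  set.seed(21)
  phis <- replicate(50, {
    y <- rpois(6, 40)
    mu <- rep(c(mean(y[1:3]), mean(y[4:6])), each = 3)
    genewise_dispersion(y, mu, 0.1, "NB", groups = two_group())
  })
  expect_lt(median(phis), 1e-3)

  # DP parameter recovery at mu = 50, theta = 2
  set.seed(22)
  thetas <- replicate(400, {
    y <- dp_sample(6, 50, 2)
    mu <- rep(c(mean(y[1:3]), mean(y[4:6])), each = 3)
    genewise_dispersion(y, mu, initial_dispersion(mean(y), var(y), "DP"),
                        "DP", groups = two_group())
  })
  expect_gt(median(thetas), 1.0)
  expect_lt(median(thetas), 4.0)
  expect_lt(abs(median(log(thetas / 2))), log(2))
})

test_that("the dispersion trend reproduces constants and log-linear signals", {
  set.seed(23)
  mu <- exp(runif(300, log(5), log(5000)))
  cst <- common_dispersion(mu, rep(0.4, 300), "DP")
  expect_equal(cst, rep(0.4, 300), tolerance = 1e-6)

  truth <- exp(0.5 - 0.3 * log(mu))
  fit <- common_dispersion(mu, truth, "DP")
  expect_lt(max(abs(fit / truth - 1)), 0.01)

  perm <- sample(300)
  expect_equal(common_dispersion(mu[perm], truth[perm], "DP"), fit[perm],
               tolerance = 1e-12)

  expect_message(small <- common_dispersion(mu[1:20], truth[1:20], "DP"),
                 "fewer than 50")
  expect_equal(small, rep(median(truth[1:20]), 20))
})

test_that("the log-normal prior follows the median/MAD rules with its floor", {
  b <- 0.3
  pr <- ln_prior(rep(b, 10) * exp(c(rep(0, 7), 1, -1, 0)), rep(b, 10))
  expect_equal(pr$m0, log(b))

  pr2 <- ln_prior(0.3 * exp(c(-1, 0, 1)), rep(0.3, 3))
  expect_equal(pr2$tau, 1.4826, tolerance = 1e-4)

  pr3 <- ln_prior(rep(0.3, 5), rep(0.3, 5))
  expect_equal(pr3$tau, 0.25)
  expect_error(ln_prior(numeric(0), numeric(0)), "non-empty")
})

test_that("shrinkage pulls outliers toward the prior and vanishes with information", {
  # outlier vs a tight prior moves toward the prior location
  set.seed(24)
  y <- dp_sample(6, 100, 8)   # strongly underdispersed gene
  mu <- rep(c(mean(y[1:3]), mean(y[4:6])), each = 3)
  gw <- genewise_dispersion(y, mu, 8, "DP", groups = two_group())
  pr <- list(m0 = log(0.5), tau = 0.25)
  sh <- shrink_dispersion(y, mu, gw, pr, "DP", groups = two_group())
  expect_lt(abs(log(sh) - pr$m0), abs(log(gw) - pr$m0))

  # with many samples a very wide prior leaves the MLE untouched
  set.seed(25)
  y2 <- dp_sample(400, 30, 1.5)
  mu2 <- rep(mean(y2), 400)
  gw2 <- genewise_dispersion(y2, mu2, 1, "DP")
  sh2 <- shrink_dispersion(y2, mu2, gw2, list(m0 = 0, tau = 100), "DP")
  expect_lt(abs(log(sh2 / gw2)), 0.01)
  expect_error(shrink_dispersion(y2, mu2, gw2, list(m0 = 0, tau = 0), "DP"),
               "tau")
})

test_that("window scan reproduces the hand-traced I/II-type medians", {
  mu <- c(1.0, 1.1, 1.2, 1.3)
  shr <- c(0.1, 0.2, 0.3, 0.4)
  com <- rep(0.25, 4)
  nb <- window_scan(mu, shr, com, "NB", gene_id = paste0("g", 1:4))
  expect_equal(nb$final, c(0.15, 0.2, 0.35, 0.4))
  dp <- window_scan(mu, shr, com, "DP", gene_id = paste0("g", 1:4))
  expect_equal(dp$final, c(0.1, 0.15, 0.3, 0.35))
  expect_equal(nb$type, c("II", "II", "I", "I"))
})

test_that("window scan is permutation-stable, respects occupancy, and keeps constants", {
  set.seed(26)
  mu <- exp(runif(200, 0, 7))
  shr <- exp(rnorm(200, 0, 0.5))
  com <- rep(1, 200)
  a <- window_scan(mu, shr, com, "DP", gene_id = sprintf("g%03d", 1:200))
  perm <- sample(200)
  b <- window_scan(mu[perm], shr[perm], com[perm], "DP",
                   gene_id = sprintf("g%03d", 1:200)[perm])
  expect_equal(b$final, a$final[perm])
  expect_true(all(table(a$window) >= 20) || length(unique(a$window)) == 1)

  flat <- window_scan(mu, rep(0.7, 200), com, "NB",
                      gene_id = sprintf("g%03d", 1:200))
  expect_equal(flat$final, rep(0.7, 200))
})

test_that("the full cascade returns a complete table with a fitted prior", {
  sim <- simulate_dataset(synth_params(120, seed = 31, mu_range = c(5, 500)),
                          n_de = 0, seed = 31)
  d <- suppressMessages(
    estimate_dispersions(sim$counts, sim$condition, rep(1, 6), family = "DP"))
  expect_true(all(c("init", "genewise", "common", "shrinkage", "final",
                    "window") %in% names(d)))
  expect_true(all(is.finite(d$final)))
  expect_true(all(d$final >= 1e-4 & d$final <= 1e4))
  pr <- attr(d, "prior")
  expect_s3_class(pr, "ln_prior")
  expect_gte(pr$tau, 0.25)
  dn <- suppressMessages(
    estimate_dispersions(sim$counts, sim$condition, rep(1, 6), family = "NB"))
  expect_true(all(dn$final >= 1e-8))
})
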