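# Wald testing, multiple-testing adjustment, DEG calling, and the main
# two-group pipeline.

#' Wald statistic for a two-group mean difference
#'
#' `W = |mu_1 - mu_2| / sqrt(sigma2_1 + sigma2_2)`.  A zero denominator gives
#' `W = 0` when the means agree and `Inf` (p = 0 downstream) when they differ.
#'
#' @param mu_1,mu_2 Group means (vectors).
#' @param sigma2_1,sigma2_2 Group variances (vectors, `>= 0`).
#' @return Numeric vector of non-negative Wald statistics.
#' @export
wald_statistic <- function(mu_1, mu_2, sigma2_1, sigma2_2) {
  if (any(sigma2_1 < 0) || any(sigma2_2 < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  num <- abs(mu_1 - mu_2)
  den <- sqrt(sigma2_1 + sigma2_2)
  w <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  as.numeric(w)
}

#' Two-sided Wald p-value
#'
#' `p = 2 * (1 - Phi(W))` with `Phi` the standard normal CDF.
#'
#' @param W Vector of non-negative Wald statistics (`Inf` allowed).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
wald_pvalue <- function(W) {
  if (any(W < 0, na.rm = TRUE)) stop("W must be non-negative", call. = FALSE)
  2 * pnorm(W, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fold change of normalized group means
#'
#' `fc = mean_2 / mean_1` (treatment over control).  Both means zero gives 1;
#' a zero control mean with expressed treatment gives `Inf`, which counts as
#' exceeding any upper fold-change threshold.
#'
#' @param mean_1,mean_2 Non-negative normalized group means.
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(mean_1, mean_2) {
  if (any(mean_1 < 0) || any(mean_2 < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  ifelse(mean_1 == 0, ifelse(mean_2 == 0, 1, Inf), mean_2 / mean_1)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its adjusted p-value is strictly below `alpha` and its
#' fold change falls strictly outside `[fc_low, fc_high]`.
#'
#' @param padj Vector of adjusted p-values.
#' @param fc Vector of fold changes (`Inf` allowed).
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @param fc_low,fc_high Fold-change bounds. Defaults 0.67 and 1.5.
#' @return Logical vector of DEG flags.
#' @export
call_degs <- function(padj, fc, alpha = 0.05, fc_low = 0.67, fc_high = 1.5) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  padj < alpha & (fc < fc_low | fc > fc_high)
}

# model variance of the normalized group mean:
#   Var(Xbar_k) = J^-2 sum_j Var(Y_jk) / s_jk^2 with Var(Y) at mean xbar*s_jk
.group_mean_variance <- function(xbar, s_group, disp, family) {
  j <- length(s_group)
  inv <- sum(1 / s_group)
  if (family == "DP") {
    xbar * inv / (disp * j^2)
  } else {
    (xbar * inv + j * xbar^2 * disp) / j^2
  }
}

#' Two-group differential expression with the double Poisson pipeline
#'
#' The full pipeline: all-zero genes are filtered, size factors estimated,
#' the five-stage dispersion cascade run per model family, and each gene
#' tested with a Wald statistic whose group variances come from the final
#' dispersions.  `mode = "DP"` or `"NB"` uses that family's p-values;
#' `mode = "Mix"` takes the per-gene minimum of the DP and NB p-values as the
#' final p-value.  BH adjustment is applied after mode selection.  The first
#' factor level of `condition` (or the first label encountered) is the
#' control group; fold changes are treatment over control.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param condition Per-sample labels with exactly two groups, each with at
#'   least 2 replicates.
#' @param mode `"Mix"` (default), `"DP"`, or `"NB"`.
#' @param normalization Size-factor method, see [compute_size_factors()].
#' @param alpha Significance level for DEG calling. Default 0.05.
#' @param fc_bounds Fold-change bounds for DEG calling. Default c(0.67, 1.5).
#' @param window_width,min_window_genes Window-scan settings.
#' @param span Lowess span for the dispersion trend. Default 0.3.
#' @param variance_of_mean If `TRUE` (default) the Wald variances are the
#'   model variances of the group means (variance of a single observation
#'   divided by the number of replicates, size-factor adjusted).  `FALSE`
#'   uses the single-observation model variance at the group mean.
#' @return An object of class `dpseq_fit`; see [tidy.dpseq_fit()] for the
#'   per-gene table and [glance.dpseq_fit()] for the one-row summary.
#' @examples
#' sim <- simulate_dataset(synth_params(300, seed = 1), n_de = 60, seed = 1)
#' fit <- dpseq(sim$counts, sim$condition, mode = "DP")
#' fit
#' head(tidy(fit))
#' @export
dpseq <- function(counts, condition, mode = c("Mix", "DP", "NB"),
                  normalization = "tmm", alpha = 0.05,
                  fc_bounds = c(0.67, 1.5), window_width = 1,
                  min_window_genes = 20, span = 0.3,
                  variance_of_mean = TRUE) {
  mode <- match.arg(mode)
  counts <- .validate_counts(counts)
  condition <- .validate_condition(condition, ncol(counts), n_groups = 2)

  keep <- rowSums(counts) > 0
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    message(n_filtered, " gene(s) with all-zero counts removed")
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no genes with nonzero counts", call. = FALSE)

  sf <- compute_size_factors(counts, method = normalization)
  s <- .as_sf_vector(sf, colnames(counts))
  norm <- sweep(counts, 2, s, "/")

  lev <- levels(condition)
  g1 <- condition == lev[1]
  g2 <- condition == lev[2]
  xbar1 <- rowMeans(norm[, g1, drop = FALSE])
  xbar2 <- rowMeans(norm[, g2, drop = FALSE])

  families <- switch(mode, DP = "DP", NB = "NB", Mix = c("DP", "NB"))
  disp <- list()
  priors <- list()
  for (fam in families) {
    d <- estimate_dispersions(counts, condition, s, family = fam,
                              window_width = window_width,
                              min_window_genes = min_window_genes, span = span)
    priors[[fam]] <- attr(d, "prior")
    disp[[fam]] <- d
  }

  wald_one <- function(fam) {
    fin <- disp[[fam]]$final
    if (variance_of_mean) {
      v1 <- .group_mean_variance(xbar1, s[g1], fin, fam)
      v2 <- .group_mean_variance(xbar2, s[g2], fin, fam)
      wald_statistic(xbar1, xbar2, v1, v2)
    } else {
      m1 <- xbar1 * mean(s[g1])
      m2 <- xbar2 * mean(s[g2])
      v1 <- model_moments(m1, fin, fam)$variance
      v2 <- model_moments(m2, fin, fam)$variance
      wald_statistic(m1, m2, v1, v2)
    }
  }
  W <- lapply(setNames(families, families), wald_one)
  pv <- lapply(W, wald_pvalue)

  if (mode == "Mix") {
    pvalue <- pmin(pv$DP, pv$NB)
    statistic <- pmax(W$DP, W$NB)
  } else {
    pvalue <- pv[[mode]]
    statistic <- W[[mode]]
  }
  padj <- bh_adjust(pvalue)
  fc <- fold_change(xbar1, xbar2)

  mom <- disp[[families[1]]]
  dclass <- ifelse(mom$sigma2 < mom$mu, "underdispersed", "non-underdispersed")

  res <- tibble(
    gene = rownames(counts),
    mu_1 = as.numeric(xbar1 * mean(s[g1])),
    mu_2 = as.numeric(xbar2 * mean(s[g2])),
    fc = as.numeric(fc),
    log2fc = log2(fc),
    statistic = as.numeric(statistic),
    pvalue = as.numeric(pvalue),
    padj = as.numeric(padj),
    deg = call_degs(padj, fc, alpha, fc_bounds[1], fc_bounds[2]),
    dispersion_class = dclass,
    mode = mode
  )
  if ("DP" %in% families) res$pvalue_dp <- as.numeric(pv$DP)
  if ("NB" %in% families) res$pvalue_nb <- as.numeric(pv$NB)

  structure(list(
    results = res,
    dispersions = do.call(rbind, disp),
    priors = priors,
    size_factors = sf,
    condition = condition,
    config = list(mode = mode, normalization = normalization, alpha = alpha,
                  fc_bounds = fc_bounds, window_width = window_width,
                  min_window_genes = min_window_genes, span = span,
                  variance_of_mean = variance_of_mean,
                  control = lev[1], treatment = lev[2]),
    n_filtered = n_filtered
  ), class = "dpseq_fit")
}

#' @export
print.dpseq_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("dpseq fit (%s mode, %s normalization)\n",
              g$mode, x$config$normalization))
  cat(sprintf("  %d genes analyzed (%d all-zero removed), %s vs %s\n",
              g$n_genes, g$n_filtered, x$config$treatment, x$config$control))
  cat(sprintf("  %d DEGs at padj < %g and fold change outside [%g, %g]\n",
              g$n_deg, g$alpha, x$config$fc_bounds[1], x$config$fc_bounds[2]))
  cat(sprintf("  %d genes (%.1f%%) underdispersed by pooled moments\n",
              g$n_underdispersed, 100 * g$n_underdispersed / g$n_genes))
  invisible(x)
}

#' Per-gene results of a dpseq fit
#'
#' @param x A [dpseq()] fit.
#' @param ... Unused.
#' @return The per-gene tibble: group means, fold change, Wald statistic,
#'   p-value, BH-adjusted p-value, DEG flag, and dispersion class.
#' @export
tidy.dpseq_fit <- function(x, ...) x$results

#' One-row summary of a dpseq fit
#'
#' @param x A [dpseq()] fit.
#' @param ... Unused.
#' @return A one-row tibble: mode, gene counts, DEG count, underdispersed
#'   count, and the fitted log-normal prior hyperparameters per family.
#' @export
glance.dpseq_fit <- function(x, ...) {
  r <- x$results
  out <- tibble(
    mode = x$config$mode,
    n_genes = nrow(r),
    n_filtered = x$n_filtered,
    n_deg = sum(r$deg),
    n_underdispersed = sum(r$dispersion_class == "underdispersed"),
    alpha = x$config$alpha
  )
  for (fam in names(x$priors)) {
    out[[paste0("m0_", tolower(fam))]] <- x$priors[[fam]]$m0
    out[[paste0("tau_", tolower(fam))]] <- x$priors[[fam]]$tau
  }
  out
}
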