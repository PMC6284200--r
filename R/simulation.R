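# DP-model dataset simulation and the dispersion classifier.
#
# The simulator draws every count from the exact DP pmf with a per-gene
# (mu, theta); a chosen subset of genes receives a fold change on the
# treatment-group mean while theta is shared between groups, matching the
# estimation assumption.  Size factors are simulated as 1: sequencing-depth
# variation is the normalizer's job, not the simulator's.  Two seed streams
# are used (one for DE selection and effect sizes, one for count draws) so the
# truth table is stable.

#' Synthetic per-gene simulation parameters
#'
#' Baseline means are log-uniform over `mu_range`; log dispersions are normal
#' with mean `theta_log_mean` and SD `theta_log_sd`, clipped to the DP bounds.
#' The defaults (`log theta ~ N(0, 0.7)`) yield a roughly even split of
#' under- (`theta > 1`) and overdispersed genes.
#'
#' @param n_genes Number of genes.
#' @param seed Optional integer seed.
#' @param mu_range Range of baseline means. Default `c(1, 1e4)`.
#' @param theta_log_sd SD of log theta. Default 0.7.
#' @param theta_log_mean Mean of log theta. Default 0.
#' @return A tibble with columns `gene`, `mu`, `theta`.
#' @export
synth_params <- function(n_genes, seed = NULL, mu_range = c(1, 1e4),
                         theta_log_sd = 0.7, theta_log_mean = 0) {
  if (n_genes < 1) stop("n_genes must be at least 1", call. = FALSE)
  if (length(mu_range) != 2L || any(mu_range <= 0) || mu_range[1] > mu_range[2]) {
    stop("mu_range must be an increasing pair of positive values", call. = FALSE)
  }
  if (theta_log_sd < 0) stop("theta_log_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- exp(runif(n_genes, log(mu_range[1]), log(mu_range[2])))
  theta <- exp(rnorm(n_genes, theta_log_mean, theta_log_sd))
  theta <- pmin(pmax(theta, .DP_MIN), .DP_MAX)
  tibble(gene = sprintf("gene_%05d", seq_len(n_genes)), mu = mu, theta = theta)
}

#' Estimate DP simulation parameters from a real count matrix
#'
#' Per gene, `mu` is the pooled mean of the normalized counts and `theta` the
#' gene-wise DP maximum-likelihood dispersion; genes with zero counts in all
#' samples are dropped.  The result feeds [simulate_dataset()] so that
#' simulations mimic a real dataset's mean and dispersion distributions.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param condition Per-sample group labels (at least 2 replicates per group).
#' @param size_factors Optional size factors; TMM when omitted.
#' @return A tibble with columns `gene`, `mu`, `theta`.
#' @export
estimate_params <- function(counts, condition, size_factors = NULL) {
  counts <- .validate_counts(counts)
  condition <- .validate_condition(condition, ncol(counts))
  keep <- rowSums(counts) > 0
  if (!all(keep)) counts <- counts[keep, , drop = FALSE]
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  s <- .as_sf_vector(size_factors, colnames(counts))
  mom <- pooled_moments(counts, condition, s)
  init <- initial_dispersion(mom$mu, mom$sigma2, "DP")
  norm <- sweep(counts, 2, s, "/")
  fitted <- matrix(0, nrow(counts), ncol(counts))
  for (lev in levels(condition)) {
    j <- condition == lev
    fitted[, j] <- rowMeans(norm[, j, drop = FALSE]) %o% s[j]
  }
  theta <- vapply(seq_len(nrow(counts)), function(i) {
    genewise_dispersion(counts[i, ], fitted[i, ], init[i], "DP",
                        groups = condition)
  }, numeric(1))
  tibble(gene = mom$gene, mu = mom$mu, theta = theta)
}

#' Simulate a two-group DP count dataset with known truth
#'
#' Draws `n_rep` replicate counts per group and gene from the exact DP pmf.
#' `n_de` randomly chosen genes receive a fold change on the group-2 mean
#' (group-1 mean stays at `mu`); all other genes have fold change exactly 1.
#' Default effect sizes: `|log2 FC|` uniform on `fc_log2_range` with random
#' sign, spanning 1.5x to 4x.  `n_de = 0` gives a null dataset for type-I
#' error studies.
#'
#' @param params Tibble with columns `gene`, `mu`, `theta` (see
#'   [synth_params()] / [estimate_params()]).
#' @param n_de Number of differentially expressed genes. Default 0.
#' @param fc Optional explicit fold-change vector for the DE genes (length
#'   `n_de`); overrides `fc_log2_range`.
#' @param fc_log2_range Range of `|log2 FC|` for DE genes.
#'   Default `c(0.585, 2)`.
#' @param n_rep Replicates per group. Default 3.
#' @param seed Integer seed. Default 1.
#' @return A list of class `dpseq_sim` with elements `counts` (matrix),
#'   `condition` (factor, levels `control`/`treatment`), and `truth` (tibble
#'   `gene`, `mu`, `theta`, `fc`, `is_de`).
#' @examples
#' sim <- simulate_dataset(synth_params(100, seed = 1), n_de = 20, seed = 1)
#' table(sim$truth$is_de)
#' @export
simulate_dataset <- function(params, n_de = 0, fc = NULL,
                             fc_log2_range = c(0.585, 2), n_rep = 3,
                             seed = 1) {
  stopifnot(is.data.frame(params), all(c("gene", "mu", "theta") %in% names(params)))
  ng <- nrow(params)
  if (n_de > ng) stop("n_de cannot exceed the number of genes", call. = FALSE)
  if (n_rep < 2) stop("need at least 2 replicates per group", call. = FALSE)

  # stream 1: truth (DE selection and effect sizes)
  set.seed(seed)
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  fc_all <- rep(1, ng)
  if (n_de > 0) {
    if (is.null(fc)) {
      mag <- runif(n_de, fc_log2_range[1], fc_log2_range[2])
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      fc <- 2^(mag * sgn)
    } else if (length(fc) != n_de) {
      stop("fc must have length n_de", call. = FALSE)
    }
    fc_all[de_idx] <- fc
  }

  # stream 2: count draws, derived so the truth stays fixed across redraws
  set.seed((seed + 104729L) %% .Machine$integer.max)
  counts <- matrix(0L, ng, 2L * n_rep)
  for (i in seq_len(ng)) {
    counts[i, seq_len(n_rep)] <- dp_sample(n_rep, params$mu[i], params$theta[i])
    counts[i, n_rep + seq_len(n_rep)] <-
      dp_sample(n_rep, params$mu[i] * fc_all[i], params$theta[i])
  }
  rownames(counts) <- params$gene
  colnames(counts) <- c(sprintf("control_%d", seq_len(n_rep)),
                        sprintf("treatment_%d", seq_len(n_rep)))

  structure(list(
    counts = counts,
    condition = factor(rep(c("control", "treatment"), each = n_rep),
                       levels = c("control", "treatment")),
    truth = tibble(gene = params$gene, mu = params$mu, theta = params$theta,
                   fc = fc_all, is_de = seq_len(ng) %in% de_idx),
    seed = seed
  ), class = "dpseq_sim")
}

#' @export
print.dpseq_sim <- function(x, ...) {
  cat(sprintf("simulated DP dataset: %d genes x %d samples, %d true DEGs (seed %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_de), x$seed))
  invisible(x)
}

#' Classify genes as underdispersed or not
#'
#' A gene is underdispersed when its pooled variance falls strictly below its
#' pooled mean (below the unit line of the log-log mean-variance plot, where
#' the unit line is the Poisson expectation); genes on the line count as
#' non-underdispersed.  Genes with zero counts everywhere are dropped.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param condition Per-sample group labels.
#' @param size_factors Optional size factors; TMM when omitted.
#' @return A tibble with columns `gene`, `mu`, `sigma2`,
#'   `dispersion_class` (`"underdispersed"` / `"non-underdispersed"`).
#' @export
classify_dispersion <- function(counts, condition, size_factors = NULL) {
  counts <- .validate_counts(counts)
  keep <- rowSums(counts) > 0
  if (!all(keep)) counts <- counts[keep, , drop = FALSE]
  mom <- pooled_moments(counts, condition, size_factors)
  mom$dispersion_class <- ifelse(mom$sigma2 < mom$mu,
                                 "underdispersed", "non-underdispersed")
  mom
}
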