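# The five-stage dispersion cascade.
#
# For each gene i, with n = sum of replicates over both groups:
#   1. moments initialization from the pooled mean mu_i and pooled variance
#      sigma2_i:  phi_init = (sigma2 - mu) / mu^2 (floored at 1e-8 when
#      sigma2 < mu, since NB cannot represent underdispersion) and
#      theta_init = mu / sigma2;
#   2. gene-wise maximum likelihood over the dispersion with the group means
#      held at their fitted values;
#   3. a common (trended) dispersion from a locally weighted regression of
#      log gene-wise dispersion on log mean;
#   4. empirical-Bayes MAP shrinkage of the gene-wise value toward a
#      log-normal prior whose location is the median log trend and whose width
#      is the MAD of the log-residuals (floored at 0.25);
#   5. a "window scan" final estimator: genes are ranked by mean, binned into
#      windows of a fixed mean width, split within each window into I-type
#      (shrinkage >= trend) and II-type (shrinkage < trend), and each gene's
#      final dispersion is the max (NB) or min (DP) of its own shrinkage value
#      and its type's median.  The max guards NB against anticonservative
#      underestimates; the min plays the symmetric role for DP, where larger
#      theta means smaller variance.
#
# Dispersions are assumed shared between the two groups, so every stage pools
# all n samples.

# ---- likelihoods ---------------------------------------------------------

# sum of DP log pmf over samples; mu per sample with at most a few unique
# values (group means scaled by size factors), so the normalizer is computed
# once per unique mean
.dp_loglik <- function(y, mu, theta) {
  ll <- 0
  for (m in unique(mu)) {
    idx <- mu == m
    yy <- y[idx]
    if (m == 0) {
      if (any(yy > 0)) return(-Inf)
    } else {
      ll <- ll + sum(.dp_lpmf_raw(yy, m, theta)) + sum(idx) * .dp_log_c(m, theta)
    }
  }
  ll
}

.nb_loglik <- function(y, mu, phi) {
  ll <- 0
  for (m in unique(mu)) {
    idx <- mu == m
    yy <- y[idx]
    if (m == 0) {
      if (any(yy > 0)) return(-Inf)
    } else if (phi < 1e-10) {
      ll <- ll + sum(dpois(yy, m, log = TRUE))
    } else {
      ll <- ll + sum(dnbinom(yy, size = 1 / phi, mu = m, log = TRUE))
    }
  }
  ll
}

.family_loglik <- function(family) {
  if (family == "NB") .nb_loglik else .dp_loglik
}

# Cox-Reid adjustment: -1/2 log of the Fisher information of each estimated
# group mean.  Plug-in group means cost degrees of freedom that the plain
# profile likelihood ignores, biasing dispersions toward too-small variances
# (for the DP family with saturated group means this term reduces exactly to
# the Gaussian REML correction, turning the n into an n - K).  `groups` is
# the per-sample group factor — one mean parameter per group; groups with a
# zero mean estimate no parameter and are skipped.
.cr_term <- function(mu, groups, disp, family) {
  tot <- 0
  for (g in unique(groups)) {
    m <- mu[groups == g]
    m <- m[m > 0]
    if (!length(m)) next
    w <- if (family == "NB") sum(m / (1 + disp * m)) else sum(disp / m)
    tot <- tot - 0.5 * log(w)
  }
  tot
}

# bounded scalar maximization in log-dispersion space; the returned value is
# the best of the interior optimum, both bounds, and the starting value, so a
# flat or monotone likelihood lands exactly on a bound and a failed search can
# never do worse than its initializer
.maximize_ldisp <- function(objective, family, init) {
  b <- log(.disp_bounds(family))
  opt <- optimize(objective, interval = b, maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, b, log(init))
  vals <- vapply(cand, objective, numeric(1))
  exp(cand[which.max(vals)])
}

# ---- cascade stages ------------------------------------------------------

#' Pooled per-gene moments
#'
#' The pooled mean `mu_i` is the mean of the normalized counts across all
#' samples times the mean size factor; the pooled variance `sigma2_i` is the
#' degrees-of-freedom-weighted within-group sample variance of the normalized
#' counts, rescaled to the same count scale.  Pooling within groups removes
#' any group-mean difference from the variance, so the moments are usable
#' under the alternative as well as the null.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param condition Per-sample group labels (any number of groups, each with
#'   at least 2 replicates).
#' @param size_factors Optional size factors (tibble or vector); TMM factors
#'   are computed when omitted.
#' @return A tibble with columns `gene`, `mu`, `sigma2`.
#' @export
pooled_moments <- function(counts, condition, size_factors = NULL) {
  counts <- .validate_counts(counts)
  condition <- .validate_condition(condition, ncol(counts))
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  s <- .as_sf_vector(size_factors, colnames(counts))
  norm <- sweep(counts, 2, s, "/")
  n <- ncol(counts)
  k <- nlevels(condition)
  sbar <- mean(s)
  xbar <- rowMeans(norm)
  ss <- 0
  for (lev in levels(condition)) {
    sub <- norm[, condition == lev, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / (n - k)
  tibble(gene = rownames(counts),
         mu = as.numeric(xbar * sbar),
         sigma2 = as.numeric(sbar^2 * v))
}

#' Moments-based initial dispersion
#'
#' NB: `(sigma2 - mu) / mu^2`, floored at `1e-8` when `sigma2 <= mu` (the NB
#' model cannot represent underdispersion, so such genes are assigned an
#' effectively-Poisson dispersion).  DP: `mu / sigma2`, clipped to
#' `[1e-4, 1e4]`; a zero variance maps to the upper bound.
#'
#' @param mu Vector of pooled per-gene means (`> 0`).
#' @param sigma2 Vector of pooled per-gene variances (`>= 0`).
#' @param family `"DP"` or `"NB"`.
#' @return Numeric vector of initial dispersions.
#' @export
initial_dispersion <- function(mu, sigma2, family = c("DP", "NB")) {
  family <- match.arg(family)
  if (any(mu <= 0)) {
    stop("mu must be positive; filter all-zero genes before the cascade", call. = FALSE)
  }
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative", call. = FALSE)
  if (family == "NB") {
    pmax((sigma2 - mu) / mu^2, .NB_MIN)
  } else {
    theta <- ifelse(sigma2 == 0, .DP_MAX, mu / sigma2)
    pmin(pmax(theta, .DP_MIN), .DP_MAX)
  }
}

#' Gene-wise maximum-likelihood dispersion
#'
#' Maximizes the log-likelihood of one gene's counts over the dispersion, with
#' the per-sample means fixed at the fitted group means scaled by each
#' sample's size factor.  The search is a bounded scalar maximization in
#' log-dispersion space started at `init`; boundary values are allowed.
#'
#' @param y Counts for one gene across all samples.
#' @param mu Per-sample fitted means (group mean of normalized counts times
#'   the sample's size factor).
#' @param init Starting dispersion (typically [initial_dispersion()]).
#' @param family `"DP"` or `"NB"`.
#' @param cr Apply the Cox-Reid adjustment for the estimated group means
#'   (default `TRUE`)?  Without it the profile likelihood systematically
#'   overestimates `theta` (underestimates variance) at small replicate
#'   numbers.
#' @param groups Per-sample group labels identifying which mean parameter
#'   each sample's fitted mean comes from (used by the Cox-Reid term).  By
#'   default each distinct value of `mu` is treated as its own group, which
#'   is correct when all size factors are equal.
#' @return The scalar dispersion estimate.
#' @export
genewise_dispersion <- function(y, mu, init, family = c("DP", "NB"), cr = TRUE,
                                groups = NULL) {
  family <- match.arg(family)
  if (is.null(groups)) groups <- match(mu, unique(mu))
  ll <- .family_loglik(family)
  obj <- if (cr) {
    function(ld) {
      d <- exp(ld)
      ll(y, mu, d) + .cr_term(mu, groups, d, family)
    }
  } else {
    function(ld) ll(y, mu, exp(ld))
  }
  .maximize_ldisp(obj, family, init)
}

#' Trended (common) dispersion
#'
#' Locally weighted regression of log gene-wise dispersion on log mean
#' (lowess, span 0.3), evaluated at every gene's mean and clipped to the
#' family bounds.  Genes of similar expression strength are assumed to share
#' similar dispersions.  With fewer than 50 genes the trend is unreliable and
#' the median gene-wise dispersion is used for all genes instead.
#'
#' Gene-wise dispersions pinned to the family bounds carry no likelihood
#' information (for NB every underdispersed gene sits exactly on the 1e-8
#' floor); letting those sentinels into the regression drags the whole trend
#' to the boundary, so only informative estimates are fit and the trend is
#' interpolated to the remaining genes.
#'
#' @param mu Vector of per-gene means (`> 0`).
#' @param genewise Vector of gene-wise dispersions.
#' @param family `"DP"` or `"NB"`.
#' @param span Lowess span. Default 0.3.
#' @return Numeric vector of trended dispersions, one per gene.
#' @export
common_dispersion <- function(mu, genewise, family = c("DP", "NB"), span = 0.3) {
  family <- match.arg(family)
  if (length(mu) != length(genewise)) stop("mu and genewise must align", call. = FALSE)
  b <- .disp_bounds(family)
  inform <- .informative_disp(genewise, family)
  if (!any(inform)) {
    return(rep(median(genewise), length(mu)))
  }
  if (sum(inform) < 50) {
    message("fewer than 50 informative genes: using their median dispersion as the trend")
    return(rep(median(genewise[inform]), length(mu)))
  }
  lx <- log(mu[inform])
  ly <- log(genewise[inform])
  o <- order(lx)
  lw <- lowess(lx[o], ly[o], f = span)
  fit <- approx(lw$x, lw$y, xout = log(mu), rule = 2, ties = mean)$y
  pmin(pmax(exp(fit), b[1]), b[2])
}

# gene-wise estimates clear of the optimization bounds; values within a
# decade of a bound are treated as boundary-pinned sentinels
.informative_disp <- function(genewise, family) {
  b <- .disp_bounds(family)
  genewise > b[1] * 10 & genewise < b[2] / 10
}

#' Log-normal shrinkage prior
#'
#' Hyperparameters of the log-normal prior used for dispersion shrinkage:
#' location `m0 = median(log(common))` and width
#' `tau = mad(log(genewise) - log(common))` (normal-consistent constant
#' 1.4826), floored at 0.25 to prevent a degenerate zero-width prior.
#'
#' @param genewise Vector of gene-wise dispersions (`> 0`).
#' @param common Vector of trended dispersions (`> 0`), same length.
#' @return A list with elements `m0` and `tau`, class `"ln_prior"`.
#' @export
ln_prior <- function(genewise, common) {
  if (length(genewise) == 0L || length(genewise) != length(common)) {
    stop("genewise and common must be non-empty vectors of equal length", call. = FALSE)
  }
  if (any(genewise <= 0) || any(common <= 0)) {
    stop("dispersions must be positive", call. = FALSE)
  }
  r <- log(genewise) - log(common)
  structure(list(m0 = median(log(common)), tau = max(mad(r), 0.25)),
            class = "ln_prior")
}

#' @export
print.ln_prior <- function(x, ...) {
  cat(sprintf("log-normal dispersion prior: m0 = %.4f (mode %.4g), tau = %.4f\n",
              x$m0, exp(x$m0), x$tau))
  invisible(x)
}

#' Empirical-Bayes shrinkage of a gene-wise dispersion
#'
#' Maximum-a-posteriori estimate under the log-normal prior: the gene's
#' log-likelihood plus the log of the log-normal prior density of the
#' dispersion is maximized, started at the gene-wise estimate.  A wide prior
#' (`tau` large) leaves the gene-wise value essentially untouched; a tight
#' prior pulls outliers toward the prior mode.  Because the density is taken
#' on the dispersion scale, the effective prior mode for the log-dispersion
#' sits at `m0 - tau^2`, a mildly conservative pull (toward larger variances
#' for the DP family) that grows with prior uncertainty.
#'
#' @param y Counts for one gene across all samples.
#' @param mu Per-sample fitted means.
#' @param genewise The gene-wise dispersion (initializer and likelihood mode).
#' @param prior An [ln_prior()] object (or list with `m0`, `tau`).
#' @param family `"DP"` or `"NB"`.
#' @param cr Apply the Cox-Reid adjustment (default `TRUE`), as in
#'   [genewise_dispersion()].
#' @param groups Per-sample group labels for the Cox-Reid term, as in
#'   [genewise_dispersion()].
#' @return The scalar MAP dispersion.
#' @export
shrink_dispersion <- function(y, mu, genewise, prior, family = c("DP", "NB"),
                              cr = TRUE, groups = NULL) {
  family <- match.arg(family)
  if (is.null(prior$m0) || is.null(prior$tau) || prior$tau <= 0) {
    stop("prior must provide m0 and tau > 0", call. = FALSE)
  }
  if (is.null(groups)) groups <- match(mu, unique(mu))
  ll <- .family_loglik(family)
  obj <- function(ld) {
    d <- exp(ld)
    ll(y, mu, d) + dlnorm(d, meanlog = prior$m0, sdlog = prior$tau, log = TRUE) +
      (if (cr) .cr_term(mu, groups, d, family) else 0)
  }
  .maximize_ldisp(obj, family, genewise)
}

# ---- window scan ---------------------------------------------------------

#' Window-scan final dispersion
#'
#' Genes are ranked by mean (ties broken by gene id), binned into consecutive
#' windows of `width` on the mean scale (windows holding fewer than
#' `min_genes` genes are merged into the next window; a small final remainder
#' is merged backward).  Within each window, genes split into I-type
#' (`shrinkage >= common`) and II-type (`shrinkage < common`).  Each gene's
#' final dispersion is the larger (NB) or smaller (DP) of its own shrinkage
#' value and the median shrinkage of its type within the window.
#'
#' @param mu Per-gene means used for ranking and windowing.
#' @param shrinkage Per-gene shrinkage dispersions.
#' @param common Per-gene trended dispersions.
#' @param family `"DP"` or `"NB"`.
#' @param width Window width in mean-count units. Default 1.
#' @param min_genes Minimum window occupancy before merging. Default 20.
#' @param gene_id Optional gene identifiers (used for tie-breaking and output).
#' @return A tibble with columns `gene`, `window`, `type`, `final`, in the
#'   input gene order.
#' @export
window_scan <- function(mu, shrinkage, common, family = c("DP", "NB"),
                        width = 1, min_genes = 20, gene_id = NULL) {
  family <- match.arg(family)
  ng <- length(mu)
  if (length(shrinkage) != ng || length(common) != ng) {
    stop("mu, shrinkage and common must align", call. = FALSE)
  }
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (is.null(gene_id)) gene_id <- sprintf("gene_%05d", seq_len(ng))

  o <- order(mu, gene_id)
  raw <- floor((mu[o] - min(mu)) / width)

  # merge-forward pass: a window below min_genes is folded into the next one
  win <- integer(ng)
  cur <- 1L
  count <- 0L
  for (i in seq_len(ng)) {
    if (i > 1L && raw[i] != raw[i - 1L] && count >= min_genes) {
      cur <- cur + 1L
      count <- 0L
    }
    win[i] <- cur
    count <- count + 1L
  }
  if (count < min_genes && cur > 1L) {
    win[win == cur] <- cur - 1L  # merge the short remainder backward
  }

  shr <- shrinkage[o]
  com <- common[o]
  fin <- numeric(ng)
  typ <- ifelse(shr >= com, "I", "II")
  pick <- if (family == "NB") pmax else pmin
  for (w in unique(win)) {
    for (tp in c("I", "II")) {
      idx <- which(win == w & typ == tp)
      if (length(idx)) fin[idx] <- pick(shr[idx], median(shr[idx]))
    }
  }

  out <- tibble(gene = gene_id[o], window = win, type = typ, final = fin)
  out[match(gene_id, out$gene), ]
}

# ---- orchestrator --------------------------------------------------------

#' Run the full dispersion cascade
#'
#' Applies all five stages to every gene for one model family and returns the
#' full dispersion table.  Genes with zero counts in all samples are removed
#' first (their moments are undefined); genes expressed in only one group are
#' retained.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param condition Per-sample two-group labels, each group with at least 2
#'   replicates.
#' @param size_factors Optional size factors; TMM when omitted.
#' @param family `"DP"` or `"NB"`.
#' @param window_width Window width for the final stage. Default 1.
#' @param min_window_genes Minimum window occupancy. Default 20.
#' @param span Lowess span for the trend. Default 0.3.
#' @return A tibble with one row per analyzed gene and columns `gene`, `mu`,
#'   `sigma2`, `init`, `genewise`, `common`, `shrinkage`, `final`, `window`,
#'   `family`; the fitted [ln_prior()] is attached as attribute `prior`.
#' @export
estimate_dispersions <- function(counts, condition, size_factors = NULL,
                                 family = c("DP", "NB"), window_width = 1,
                                 min_window_genes = 20, span = 0.3) {
  family <- match.arg(family)
  counts <- .validate_counts(counts)
  condition <- .validate_condition(condition, ncol(counts))
  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    message(sum(!keep), " gene(s) with all-zero counts removed")
    counts <- counts[keep, , drop = FALSE]
  }
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  s <- .as_sf_vector(size_factors, colnames(counts))

  mom <- pooled_moments(counts, condition, s)
  init <- initial_dispersion(mom$mu, mom$sigma2, family)

  # fitted per-sample means: normalized group mean times the sample's factor
  norm <- sweep(counts, 2, s, "/")
  fitted <- matrix(0, nrow(counts), ncol(counts))
  for (lev in levels(condition)) {
    j <- condition == lev
    fitted[, j] <- rowMeans(norm[, j, drop = FALSE]) %o% s[j]
  }

  ng <- nrow(counts)
  genewise <- vapply(seq_len(ng), function(i) {
    genewise_dispersion(counts[i, ], fitted[i, ], init[i], family,
                        groups = condition)
  }, numeric(1))

  common <- common_dispersion(mom$mu, genewise, family, span = span)
  inform <- .informative_disp(genewise, family)
  prior <- if (any(inform)) {
    ln_prior(genewise[inform], common[inform])
  } else {
    ln_prior(genewise, common)
  }
  shrunk <- vapply(seq_len(ng), function(i) {
    shrink_dispersion(counts[i, ], fitted[i, ], genewise[i], prior, family,
                      groups = condition)
  }, numeric(1))

  ws <- window_scan(mom$mu, shrunk, common, family, width = window_width,
                    min_genes = min_window_genes, gene_id = mom$gene)

  out <- tibble(gene = mom$gene, mu = mom$mu, sigma2 = mom$sigma2,
                init = init, genewise = genewise, common = common,
                shrinkage = shrunk, final = ws$final, window = ws$window,
                family = family)
  attr(out, "prior") <- prior
  out
}
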