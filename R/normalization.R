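# Size-factor estimation and count normalization.
#
# Normalized counts estimate the underlying expression X via Y / s, where the
# per-sample size factor s absorbs sequencing depth and composition effects.
# All methods rescale so the geometric mean of the size factors is one, which
# anchors the normalized scale without preferring any sample.

.geo_rescale <- function(s) s / exp(mean(log(s)))

.as_sf_vector <- function(size_factors, sample_ids = NULL) {
  if (is.data.frame(size_factors)) {
    s <- size_factors$size_factor
    names(s) <- size_factors$sample
  } else {
    s <- size_factors
  }
  if (!is.null(sample_ids) && !is.null(names(s)) && all(sample_ids %in% names(s))) {
    s <- s[sample_ids]
  }
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  unname(s)
}

#' Estimate per-sample size factors
#'
#' Computes one positive scale factor per sample (library), rescaled so that
#' their geometric mean is 1.  The default is TMM (trimmed mean of M-values):
#' the reference sample is the one whose upper quartile is closest to the mean
#' upper quartile, and each sample's factor is a weighted mean of trimmed
#' log-ratios against the reference (30% M-trim, 5% A-trim,
#' inverse-asymptotic-variance weights), times library size.  `"deseq"` is the
#' median-of-ratios method over genes with all-positive counts;
#' `"upper_quartile"`, `"median"`, and `"total"` scale by the named per-sample
#' statistic.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param method One of `"tmm"`, `"total"`, `"upper_quartile"`, `"median"`,
#'   `"deseq"`.
#' @return A tibble with columns `sample` and `size_factor` and attribute
#'   `method`.
#' @examples
#' m <- matrix(rpois(600, 20), 100, 6,
#'             dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
#' compute_size_factors(m)
#' @export
compute_size_factors <- function(counts,
                                 method = c("tmm", "total", "upper_quartile",
                                            "median", "deseq")) {
  method <- match.arg(method)
  counts <- .validate_counts(counts)
  ns <- ncol(counts)
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (ns == 1L) {
    s <- 1
  } else if (method %in% c("tmm", "upper_quartile")) {
    em <- if (method == "tmm") "TMM" else "upperquartile"
    f <- suppressWarnings(edgeR::calcNormFactors(counts, method = em))
    if (any(!is.finite(f))) {
      message("normalization factors undefined for some samples; falling back to total counts")
      f[!is.finite(f)] <- 1
    }
    s <- .geo_rescale(colSums(counts) * f)
  } else if (method == "total") {
    s <- .geo_rescale(colSums(counts))
  } else if (method == "median") {
    s <- .geo_rescale(apply(counts, 2, function(x) median(x[x > 0])))
  } else { # deseq: median of ratios to the geometric-mean pseudo-reference
    pos <- rowSums(counts > 0) == ns
    if (!any(pos)) stop("no genes with positive counts in every sample", call. = FALSE)
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    s <- apply(counts[pos, , drop = FALSE], 2,
               function(x) exp(median(log(x) - logref)))
    s <- .geo_rescale(s)
  }
  out <- tibble(sample = colnames(counts), size_factor = as.numeric(s))
  attr(out, "method") <- method
  out
}

#' Normalize counts by size factors
#'
#' Divides every column of the count matrix by its sample's size factor,
#' giving real-valued normalized counts on a common scale.
#'
#' @param counts Gene-by-sample matrix of non-negative counts.
#' @param size_factors Output of [compute_size_factors()] or a positive numeric
#'   vector, one per sample.
#' @return A numeric matrix of the same dimensions as `counts`.
#' @export
normalize_counts <- function(counts, size_factors) {
  counts <- .validate_counts(counts)
  s <- .as_sf_vector(size_factors, colnames(counts))
  if (length(s) != ncol(counts)) {
    stop("need one size factor per sample", call. = FALSE)
  }
  sweep(counts, 2, s, "/")
}
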