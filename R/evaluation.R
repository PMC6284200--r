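# Benchmarking metrics over truth-labeled results: FPR/TPR at a significance
# level, ROC and AUC, precision-recall, and a tidy comparison harness that
# also accepts external methods' per-gene p-value tables.

.check_binary_truth <- function(is_de) {
  if (!is.logical(is_de)) stop("is_de must be logical", call. = FALSE)
  if (anyNA(is_de)) stop("is_de must not contain NA", call. = FALSE)
}

#' False- and true-positive rates at a significance level
#'
#' `fpr` is the fraction of truly non-DE genes with `p < alpha`; `tpr` the
#' fraction of truly DE genes with `p < alpha`.  When `class` is supplied,
#' rates are also reported per dispersion class.  Empty denominators yield
#' `NA`, not 0.
#'
#' @param pvalue Per-gene p-values.
#' @param is_de Logical ground-truth DE status, aligned with `pvalue`.
#' @param alpha Significance level. Default 0.05.
#' @param class Optional per-gene stratum labels (e.g. dispersion classes).
#' @return A tibble with columns `stratum`, `n_de`, `n_null`, `fpr`, `tpr`.
#' @export
confusion_metrics <- function(pvalue, is_de, alpha = 0.05, class = NULL) {
  .check_binary_truth(is_de)
  if (length(pvalue) != length(is_de)) {
    stop("pvalue and is_de must align", call. = FALSE)
  }
  strata <- list(all = rep(TRUE, length(pvalue)))
  if (!is.null(class)) {
    for (cl in sort(unique(class))) strata[[cl]] <- class == cl
  }
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    p <- pvalue[sel]; d <- is_de[sel]
    tibble(stratum = nm,
           n_de = sum(d),
           n_null = sum(!d),
           fpr = if (any(!d)) mean(p[!d] < alpha) else NA_real_,
           tpr = if (any(d)) mean(p[d] < alpha) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

# cumulative confusion counts along decreasing significance, ties grouped
.rank_sweep <- function(pvalue, is_de) {
  o <- order(pvalue, decreasing = FALSE)
  p <- pvalue[o]; d <- is_de[o]
  keep <- !duplicated(p, fromLast = TRUE)  # last index of each tie group
  tibble(threshold = p[keep],
         tp = cumsum(d)[keep],
         fp = cumsum(!d)[keep])
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique p-values (smaller p = stronger DE call);
#' tied p-values are grouped, which makes the trapezoid AUC equal to the
#' Mann-Whitney pairwise probability with half-credit for ties.
#'
#' @param pvalue Per-gene p-values (any strictly monotone score works).
#' @param is_de Logical ground-truth DE status.
#' @return An object of class `dpseq_roc`: list with `curve` (tibble `fpr`,
#'   `tpr` starting at (0, 0) and ending at (1, 1)) and scalar `auc`.
#' @export
roc_auc <- function(pvalue, is_de) {
  .check_binary_truth(is_de)
  if (!any(is_de) || all(is_de)) {
    stop("need at least one DE and one non-DE gene", call. = FALSE)
  }
  sw <- .rank_sweep(pvalue, is_de)
  fpr <- c(0, sw$fp / sum(!is_de))
  tpr <- c(0, sw$tp / sum(is_de))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(curve = tibble(fpr = fpr, tpr = tpr), auc = auc),
            class = "dpseq_roc")
}

#' @export
print.dpseq_roc <- function(x, ...) {
  cat(sprintf("ROC curve over %d thresholds, AUC = %.4f\n",
              nrow(x$curve) - 1L, x$auc))
  invisible(x)
}

#' Precision-recall curve
#'
#' Precision and recall at every unique p-value threshold; precision at
#' recall 0 is defined as the precision of the top-ranked tie group.
#'
#' @param pvalue Per-gene p-values.
#' @param is_de Logical ground-truth DE status (at least one DE gene).
#' @return An object of class `dpseq_prc`: a list with `curve` (tibble
#'   `recall`, `precision`).
#' @export
pr_curve <- function(pvalue, is_de) {
  .check_binary_truth(is_de)
  if (!any(is_de)) stop("need at least one DE gene", call. = FALSE)
  sw <- .rank_sweep(pvalue, is_de)
  prec <- sw$tp / (sw$tp + sw$fp)
  rec <- sw$tp / sum(is_de)
  structure(list(curve = tibble(recall = c(0, rec),
                                precision = c(prec[1], prec))),
            class = "dpseq_prc")
}

#' @export
print.dpseq_prc <- function(x, ...) {
  cat(sprintf("precision-recall curve over %d thresholds\n",
              nrow(x$curve) - 1L))
  invisible(x)
}

.standardize_result_table <- function(tab, method) {
  tab <- as.data.frame(tab)
  gcol <- intersect(c("gene", "gene_id"), names(tab))[1]
  if (is.na(gcol) || !"pvalue" %in% names(tab)) {
    stop(sprintf("method '%s': result table needs gene/gene_id and pvalue columns",
                 method), call. = FALSE)
  }
  tibble(gene = as.character(tab[[gcol]]), pvalue = as.numeric(tab$pvalue),
         fc = if ("fc" %in% names(tab)) as.numeric(tab$fc) else NA_real_)
}

#' Compare DE methods against a simulation truth
#'
#' For each method's per-gene p-value table, computes FPR, TPR (at `alpha`,
#' raw p-values), AUC, and the DEG count (BH-adjusted `p < alpha`, plus the
#' fold-change rule when the table carries an `fc` column), overall and per
#' stratum.  Genes missing from a method's table are scored as `p = 1`.
#'
#' @param tables Named list of data frames, each with columns `gene` (or
#'   `gene_id`) and `pvalue`, optionally `fc`.
#' @param truth Truth table with columns `gene` and `is_de` (e.g. the `truth`
#'   element of [simulate_dataset()]).
#' @param alpha Significance level. Default 0.05.
#' @param classes Optional per-gene strata: a data frame with columns `gene`
#'   and `dispersion_class` (e.g. from [classify_dispersion()]).
#' @param replicate Optional replicate identifier echoed into the output.
#' @return A tidy tibble: `method`, `stratum`, `replicate`, `fpr`, `tpr`,
#'   `auc`, `n_deg`.
#' @export
compare_methods <- function(tables, truth, alpha = 0.05, classes = NULL,
                            replicate = NA_integer_) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list", call. = FALSE)
  }
  truth <- as.data.frame(truth)
  gcol <- intersect(c("gene", "gene_id"), names(truth))[1]
  genes <- as.character(truth[[gcol]])
  is_de <- as.logical(truth$is_de)
  cls <- NULL
  if (!is.null(classes)) {
    classes <- as.data.frame(classes)
    cls <- classes$dispersion_class[match(genes, classes$gene)]
    cls[is.na(cls)] <- "unclassified"
  }

  out <- lapply(names(tables), function(nm) {
    tab <- .standardize_result_table(tables[[nm]], nm)
    idx <- match(genes, tab$gene)
    if (anyNA(idx)) {
      message(sprintf("method '%s': %d gene(s) missing; scored as p = 1",
                      nm, sum(is.na(idx))))
    }
    p <- ifelse(is.na(idx), 1, tab$pvalue[idx])
    fc <- ifelse(is.na(idx), 1, tab$fc[idx])
    padj <- bh_adjust(p)
    deg <- if (all(is.na(fc))) padj < alpha else call_degs(padj, fc, alpha)
    cm <- confusion_metrics(p, is_de, alpha, class = cls)
    cm$method <- nm
    cm$replicate <- replicate
    cm$auc <- vapply(seq_len(nrow(cm)), function(r) {
      sel <- if (cm$stratum[r] == "all") rep(TRUE, length(p)) else cls == cm$stratum[r]
      if (any(is_de[sel]) && any(!is_de[sel])) roc_auc(p[sel], is_de[sel])$auc else NA_real_
    }, numeric(1))
    cm$n_deg <- vapply(seq_len(nrow(cm)), function(r) {
      sel <- if (cm$stratum[r] == "all") rep(TRUE, length(p)) else cls == cm$stratum[r]
      sum(deg[sel], na.rm = TRUE)
    }, numeric(1))
    cm
  })
  dplyr::bind_rows(out)[, c("method", "stratum", "replicate", "n_de", "n_null",
                            "fpr", "tpr", "auc", "n_deg")]
}
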