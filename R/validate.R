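# Input validation shared across the package.

.validate_counts <- function(counts, require_integer = TRUE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric gene-by-sample matrix", call. = FALSE)
  }
  if (anyNA(counts)) stop("counts must not contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 .dim_label(rownames(counts), idx[1], "gene"),
                 .dim_label(colnames(counts), idx[2], "sample")), call. = FALSE)
  }
  if (require_integer && any(counts != floor(counts))) {
    idx <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 .dim_label(rownames(counts), idx[1], "gene"),
                 .dim_label(colnames(counts), idx[2], "sample")), call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifiers in counts", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  }
  counts
}

.dim_label <- function(nms, i, what) {
  if (is.null(nms)) paste0(what, " #", i) else nms[i]
}

.validate_condition <- function(condition, n_samples, n_groups = NULL,
                                min_reps = 2L) {
  condition <- as.factor(condition)
  condition <- droplevels(condition)
  if (length(condition) != n_samples) {
    stop("condition must have one label per sample", call. = FALSE)
  }
  if (anyNA(condition)) stop("condition must not contain missing labels", call. = FALSE)
  if (!is.null(n_groups) && nlevels(condition) != n_groups) {
    stop(sprintf("condition must have exactly %d groups (got %d)",
                 n_groups, nlevels(condition)), call. = FALSE)
  }
  if (any(table(condition) < min_reps)) {
    stop(sprintf("every group needs at least %d replicates", min_reps),
         call. = FALSE)
  }
  condition
}
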