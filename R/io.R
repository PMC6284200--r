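# Delimited-text round-tripping for count matrices and result tables.
# Format: first column gene identifiers, header row of sample identifiers;
# the delimiter is auto-detected between tab and comma.

#' Read a count matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the delimiter (tab or comma) is detected from the header.
#' Duplicate gene identifiers, negative values, and non-integer values are
#' rejected with the offending gene and sample named.
#'
#' @param path Path to the file.
#' @return A gene-by-sample integer-valued matrix with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("need a gene-id column plus at least one sample", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  rownames(m) <- ids
  .validate_counts(m)
}

#' Write a count matrix as delimited text
#'
#' @param counts Gene-by-sample matrix.
#' @param path Output path.
#' @param sep Delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, sep = "\t") {
  counts <- .validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as delimited text
#'
#' Numbers are rendered with 6 significant digits; infinite fold changes are
#' written as the literal token `Inf` and missing values as `NA`.
#'
#' @param x A [dpseq()] fit or a per-gene results data frame.
#' @param path Output path.
#' @param sep Delimiter. Default tab.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, sep = "\t") {
  if (inherits(x, "dpseq_fit")) x <- tidy(x)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
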