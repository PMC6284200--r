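# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no data files are read.

two_group <- function(n_rep = 3) {
  factor(rep(c("a", "b"), each = n_rep), levels = c("a", "b"))
}

# small deterministic count matrix with gene/sample names
toy_counts <- function(values, n_genes = NULL, n_samples = 6) {
  m <- matrix(values, ncol = n_samples, byrow = TRUE)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

# seeded Poisson count matrix
pois_counts <- function(n_genes, n_samples, lambda, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", seq_len(n_samples))
  m
}

# brute-force BH step-up oracle: sort ascending, take the running minimum of
# m * p_(j) / j from the right, map back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, min(1, m * ps[j] / j))
    adj[k] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney pairwise AUC oracle with half-credit for ties
mw_auc_oracle <- function(pvalue, is_de) {
  sc <- -pvalue
  d <- sc[is_de]
  nd <- sc[!is_de]
  s <- 0
  for (a in d) s <- s + sum(a > nd) + 0.5 * sum(a == nd)
  s / (length(d) * length(nd))
}
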