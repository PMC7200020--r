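# Shared builders for small in-code fixtures.

# genes x samples matrix of iid normals with dimnames
rand_expr <- function(genes, nsamples, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(genes) * nsamples, sd = sd),
              length(genes), nsamples,
              dimnames = list(genes, sprintf("S%02d", seq_len(nsamples))))
  m
}

# write a genes x samples matrix to a temporary TSV, returning the path
write_tsv_matrix <- function(m, corner = "gene_id") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- corner
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric test
hyper_tail_enum <- function(N, M, K, L) {
  if (L == 0) return(1)
  i <- 0:(L - 1)
  1 - sum(choose(M, i) * choose(N - M, K - i)) / choose(N, K)
}

# brute-force step-up BH oracle
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    i <- ord[r]
    adj[i] <- min(vapply(r:m, function(j) p[ord[j]] * m / j, 0), 1)
  }
  adj
}

# triple-loop topological overlap oracle
tom_brute <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# the standard small simulation scenario used across tests
default_sim <- function(seed = 7) simulateSpongeDataset(seed = seed)
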