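# Independent oracle implementations used to cross-check the package. Each is
# a deliberately naive, loop-level computation kept separate from the code
# paths it verifies.

# ssGSEA running-sum integral, naive position-by-position walk
oracle_es <- function(expr, sig, alpha_w = 0.25) {
  G <- length(expr)
  ord <- order(-expr)
  genes <- names(expr)[ord]
  hit <- genes %in% sig
  k <- sum(hit)
  wsum <- 0
  for (i in seq_len(G)) if (hit[i]) wsum <- wsum + (G - i + 1)^alpha_w
  running <- 0
  es <- 0
  for (i in seq_len(G)) {
    if (hit[i]) running <- running + (G - i + 1)^alpha_w / wsum
    else running <- running - 1 / (G - k)
    es <- es + running
  }
  es
}

# average ranks computed by counting, then the plain Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# non-negative least squares on the standardized system (independent solver)
oracle_nnls_fractions <- function(m, B, scheme = "global") {
  std <- standardize(m, B, scheme)
  w <- pracma::lsqnonneg(std$B, std$m)$x
  w / sum(w)
}

# small toy signature matrix with distinct marker blocks, fixed values
toy_B <- function(n_genes = 12, n_types = 3, high = 100, low = 1) {
  B <- matrix(low, n_genes, n_types,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("t", seq_len(n_types))))
  block <- n_genes %/% n_types
  for (k in seq_len(n_types))
    B[((k - 1) * block + 1):(k * block), k] <- high
  # break exact symmetry so no column is a permutation of another
  B <- B * matrix(seq(1, 1.5, length.out = n_genes), n_genes, n_types)
  B
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
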