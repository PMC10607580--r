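# Shared fixtures and independent oracles used across test files.

# Small expression matrix with named dims.
toy_expression <- function(n_genes = 3, n_samples = 2, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples, 7, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(v, labels = labels)
}

# Signed block network: within-block weight `w_in`, between `w_out`.
block_network <- function(sizes, w_in = 0.9, w_out = -0.3) {
  n <- sum(sizes)
  memb <- rep(seq_along(sizes), sizes)
  W <- matrix(w_out, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(memb == b)
    W[idx, idx] <- w_in
  }
  diag(W) <- 0
  ids <- sprintf("g%03d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  coexcomm:::new_network(W, ids, "pearson")
}

# Brute-force NMI from the joint contingency table (natural logs).
# Independent of the package implementation.
nmi_oracle <- function(a, b) {
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        mi <- mi + (tab[i, j] / n) *
          log((tab[i, j] / n) / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  ent <- function(x) {
    p <- x / sum(x)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(rowSums(tab))
  hb <- ent(colSums(tab))
  if (ha + hb == 0) return(1)
  2 * mi / (ha + hb)
}

# Brute-force AUC by looping over every positive/negative pair.
auc_oracle <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  100 * s / (length(pos) * length(neg))
}

random_partition <- function(genes, k, seed) {
  set.seed(seed)
  stats::setNames(sample.int(k, length(genes), replace = TRUE), genes)
}
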