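#' Build a signed co-expression network
#'
#' Nodes are genes; the edge weight between two genes is the correlation of
#' their expression profiles across samples, sign preserved. The network is
#' kept complete (no hard thresholding): the signed community objective
#' consumes the full weight matrix directly. An optional soft threshold
#' zeroes weak edges for sensitivity analyses.
#'
#' @param m an [expression_matrix()] with >= 3 samples.
#' @param method correlation measure, `"pearson"` (default) or
#'   `"spearman"`.
#' @param soft_threshold optional numeric in (0, 1): absolute weights below
#'   it are set to 0. Default `NULL` (off).
#' @return a `CoexpressionNetwork`: list with `gene_ids`, `weights`
#'   (symmetric, zero diagonal, entries in \[-1, 1\]) and
#'   `correlation_method`. Constant (zero-variance) genes are dropped with
#'   a warning.
#' @export
build_network <- function(m, method = c("pearson", "spearman"),
                          soft_threshold = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  method <- match.arg(method)
  if (ncol(m$values) < 3) stop("need >= 3 samples to estimate correlations")
  v <- apply(m$values, 1, var)
  if (all(v == 0)) stop("all genes are constant; no network to build")
  if (any(v == 0)) {
    dropped <- m$gene_ids[v == 0]
    warning("dropping ", length(dropped), " constant gene(s): ",
            paste(head(dropped, 5), collapse = ", "))
    m <- subset_expression(m, genes = m$gene_ids[v > 0])
  }
  W <- cor(t(m$values), method = method)
  diag(W) <- 0
  if (!is.null(soft_threshold)) {
    W[abs(W) < soft_threshold] <- 0
  }
  new_network(W, m$gene_ids, method)
}

new_network <- function(W, gene_ids, method) {
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(
    list(gene_ids = gene_ids, weights = W, correlation_method = method),
    class = "CoexpressionNetwork"
  )
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d genes (%s), mean |w| = %.3f\n",
              length(x$gene_ids), x$correlation_method,
              mean(abs(x$weights[upper.tri(x$weights)]))))
  invisible(x)
}

#' Extract the subnetwork induced by a gene subset
#'
#' Edge weights are inherited (the principal submatrix), not recomputed
#' from expression: during hierarchical detection the community-detection
#' step is applied to subnetworks of the one original network.
#'
#' @param net a `CoexpressionNetwork`.
#' @param genes character vector, a subset of `net$gene_ids`.
#' @return a `CoexpressionNetwork` over `genes`, in the given order.
#' @export
subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  unknown <- setdiff(genes, net$gene_ids)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(head(unknown, 5), collapse = ", "))
  }
  new_network(net$weights[genes, genes, drop = FALSE], genes,
              net$correlation_method)
}

#' Export the network as an edge list
#'
#' @param net a `CoexpressionNetwork`.
#' @param path optional TSV path; when `NULL` the data frame is returned
#'   only.
#' @return data frame (gene_a, gene_b, weight), upper triangle only.
#' @export
network_edge_list <- function(net, path = NULL) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  idx <- which(upper.tri(net$weights), arr.ind = TRUE)
  df <- data.frame(gene_a = net$gene_ids[idx[, 1]],
                   gene_b = net$gene_ids[idx[, 2]],
                   weight = net$weights[idx],
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
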