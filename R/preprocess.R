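#' Log2-transform an expression matrix
#'
#' @param m an [expression_matrix()].
#' @param offset non-negative pseudo-count added before taking log2.
#' @return transformed `ExpressionMatrix`.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"), offset >= 0)
  v <- m$values + offset
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value at gene '%s', sample '%s' (offset %g)",
                 m$gene_ids[idx[1]], m$sample_ids[idx[2]], offset))
  }
  expression_matrix(log2(v), labels = m$labels)
}

#' Quantile-normalize samples of an expression matrix
#'
#' Each sample's values are replaced by the rank-wise means of the sorted
#' sample columns, so afterwards every column carries the identical sorted
#' value multiset. Ties receive the average of the reference values over the
#' tied rank span. Delegates to [limma::normalizeQuantiles()], the standard
#' microarray implementation of exactly this convention.
#'
#' @param m an [expression_matrix()] with at least two samples.
#' @return normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2) {
    stop("quantile normalization needs >= 2 samples (no reference distribution)")
  }
  out <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(out) <- dimnames(m$values)
  expression_matrix(out, labels = m$labels)
}

#' Cluster samples with k-means
#'
#' Samples (columns) are the clustered units, in the full gene space with
#' Euclidean distance, using best-of-`n_starts` Lloyd iterations.
#'
#' @param m an [expression_matrix()].
#' @param k number of clusters (`k <= n_samples`).
#' @param n_starts random restarts; the lowest-WSS solution is kept.
#' @param seed integer seed (deterministic result).
#' @param top_var_genes optional integer: cluster on only this many
#'   top-variance genes instead of all genes.
#' @return named integer vector sample -> cluster id.
#' @export
kmeans_cluster <- function(m, k, n_starts = 25, seed = 1L,
                           top_var_genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  X <- t(m$values)
  if (!is.null(top_var_genes)) {
    v <- apply(m$values, 1, var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(min(top_var_genes, length(v)))]
    X <- X[, keep, drop = FALSE]
  }
  if (k > nrow(X)) stop("k exceeds the number of samples")
  fit <- with_seed(seed, suppressWarnings(
    kmeans(X, centers = k, nstart = n_starts, iter.max = 100,
           algorithm = "Lloyd")))
  stats::setNames(fit$cluster, rownames(X))
}

#' Within-cluster sum of squares and silhouette diagnostics
#'
#' Computes WSS for k = 1..k_max and the mean silhouette coefficient for
#' k = 2..k_max over sample clusterings; `chosen_k` is the silhouette
#' maximizer (the elbow on the WSS curve is reported via the curve itself,
#' not automated).
#'
#' @inheritParams kmeans_cluster
#' @param k_max largest k to evaluate (>= 2).
#' @return a `ClusterDiagnostics` list: `k_values`, `wss`, `silhouette`
#'   (NA at k = 1), `chosen_k`.
#' @export
cluster_diagnostics <- function(m, k_max = 8, n_starts = 25, seed = 1L,
                                top_var_genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), k_max >= 2)
  X <- t(m$values)
  if (!is.null(top_var_genes)) {
    v <- apply(m$values, 1, var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(min(top_var_genes, length(v)))]
    X <- X[, keep, drop = FALSE]
  }
  if (all(stats::dist(X) < 1e-12)) {
    stop("all samples identical: silhouette undefined")
  }
  k_values <- seq_len(min(k_max, nrow(X) - 1))
  d <- stats::dist(X)
  wss <- numeric(length(k_values))
  sil <- rep(NA_real_, length(k_values))
  grand <- colMeans(X)
  wss[1] <- sum(sweep(X, 2, grand)^2)
  for (i in seq_along(k_values)[-1]) {
    k <- k_values[i]
    fit <- with_seed(derive_seed(seed, k), suppressWarnings(
      kmeans(X, centers = k, nstart = n_starts, iter.max = 100,
             algorithm = "Lloyd")))
    wss[i] <- fit$tot.withinss
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  structure(
    list(k_values = k_values, wss = wss, silhouette = sil,
         chosen_k = k_values[which.max(sil)]),
    class = "ClusterDiagnostics"
  )
}

#' Class/cluster contingency agreement
#'
#' Builds the class x cluster contingency table and reports the percentage
#' of samples from a designated class union that fall into that union's
#' joint majority cluster (ties broken toward the lower cluster id).
#'
#' @param labels named character vector sample -> class.
#' @param clusters named integer vector sample -> cluster id (same samples).
#' @param merge_classes non-empty character vector of classes to pool.
#' @return a `ContingencyResult` list: `table`, `agreement_pct`,
#'   `majority_cluster`.
#' @export
contingency_agreement <- function(labels, clusters, merge_classes) {
  if (!length(merge_classes)) stop("merge_classes must be non-empty")
  if (!setequal(names(labels), names(clusters))) {
    stop("labels and clusters must cover the same samples")
  }
  clusters <- clusters[names(labels)]
  tab <- table(class = labels, cluster = clusters)
  sel <- labels %in% merge_classes
  if (!any(sel)) stop("no samples belong to the merge classes")
  counts <- table(clusters[sel])
  maj <- names(counts)[which.max(counts)]  # first max = lowest cluster id
  structure(
    list(table = tab,
         agreement_pct = 100 * max(counts) / sum(sel),
         majority_cluster = as.integer(maj)),
    class = "ContingencyResult"
  )
}
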