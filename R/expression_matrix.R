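#' Construct an expression matrix object
#'
#' A light container for a genes x samples real-valued matrix with unique
#' gene and sample identifiers and optional per-sample class labels.
#'
#' @param values numeric matrix, genes in rows. Row names are gene ids and
#'   column names are sample ids (both required and unique).
#' @param labels optional named character vector mapping every sample id to a
#'   class (e.g. `"tumor"` / `"normal"`).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix), `gene_ids`, `sample_ids` and `labels`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m, labels = c(s1 = "tumor", s2 = "normal"))
#' @export
expression_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[idx[1]], sample_ids[idx[2]]))
  }
  if (!is.null(labels)) {
    labels <- validate_labels(labels, sample_ids)
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "ExpressionMatrix"
  )
}

validate_labels <- function(labels, sample_ids) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  if (anyDuplicated(names(labels))) {
    for (s in unique(names(labels)[duplicated(names(labels))])) {
      if (length(unique(labels[names(labels) == s])) > 1) {
        stop(sprintf("sample '%s' listed with conflicting classes", s))
      }
    }
    labels <- labels[!duplicated(names(labels))]
  }
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing)) {
    stop("labels missing for sample(s): ", paste(head(missing, 5), collapse = ", "))
  }
  as.character(labels[sample_ids]) -> out
  names(out) <- sample_ids
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Restrict an expression matrix to a subset of genes and/or samples
#'
#' @param m an [expression_matrix()].
#' @param genes,samples character vectors of ids to keep (default: all).
#'   Order is preserved as given.
#' @return an `ExpressionMatrix`.
#' @export
subset_expression <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  genes <- genes %||% m$gene_ids
  samples <- samples %||% m$sample_ids
  unknown <- setdiff(genes, m$gene_ids)
  if (length(unknown)) stop("unknown gene(s): ", paste(head(unknown, 5), collapse = ", "))
  unknown <- setdiff(samples, m$sample_ids)
  if (length(unknown)) stop("unknown sample(s): ", paste(head(unknown, 5), collapse = ", "))
  vals <- m$values[genes, samples, drop = FALSE]
  expression_matrix(vals, labels = if (!is.null(m$labels)) m$labels[samples])
}
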