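#' Read an expression matrix from a delimited text file
#'
#' The first column holds gene ids and the header holds sample ids (or the
#' transpose, with `genes_in_rows = FALSE`). The delimiter is always
#' explicit; there is no auto-detection, because silently mis-parsed
#' expression tables are a classic failure mode.
#'
#' @param path file path.
#' @param delimiter single field-separator character (default tab).
#' @param genes_in_rows if `FALSE` the file is samples x genes and is
#'   transposed after reading.
#' @param labels optional named character vector of sample classes, e.g.
#'   from [read_labels()].
#' @return an [expression_matrix()]. Gene and sample order follow the file.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   genes_in_rows = TRUE, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE,
                   colClasses = "character", row.names = NULL)
  if (ncol(df) < 2) stop("expected an id column plus at least one data column")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s",
                 if (genes_in_rows) "gene" else "sample",
                 paste(dup, collapse = ", ")))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(vals) && !all(is.na(vals) == is.na(raw))) {
    bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at row %d (id '%s'), column '%s'",
                 raw[bad[1], bad[2]], bad[1], ids[bad[1]],
                 colnames(raw)[bad[2]]))
  }
  dimnames(vals) <- list(ids, colnames(df)[-1])
  if (!genes_in_rows) vals <- t(vals)
  expression_matrix(vals, labels = labels)
}

#' Write an expression matrix to a delimited text file
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param delimiter field separator.
#' @param id_column name for the leading gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = "\t",
                                    id_column = "gene_id") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  # %.17g guarantees exact double round-trip through the text file
  chr <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values),
                dimnames = dimnames(m$values))
  df <- data.frame(m$gene_ids, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Expects a two-column delimited file with a header row
#' (`sample_id<sep>class`). A sample repeated with conflicting classes is an
#' error; a repeated consistent entry is deduplicated.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return named character vector mapping sample id to class; empty (with a
#'   warning) for a file with no data rows.
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2 && nrow(df) > 0) stop("expected two columns: sample_id, class")
  if (nrow(df) == 0) {
    warning("label file '", path, "' contains no samples")
    return(stats::setNames(character(0), character(0)))
  }
  out <- stats::setNames(df[[2]], df[[1]])
  for (s in unique(names(out)[duplicated(names(out))])) {
    if (length(unique(out[names(out) == s])) > 1) {
      stop(sprintf("sample '%s' listed with conflicting classes", s))
    }
  }
  out[!duplicated(names(out))]
}

#' Write per-sample class labels
#' @param labels named character vector (names are sample ids).
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  df <- data.frame(sample_id = names(labels), class = as.character(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a community tree's gene assignment
#'
#' One row per gene of the root network, with the community index at each
#' hierarchy depth (`NA` beyond the gene's depth) and a dense leaf id
#' (1..K). Genes from discarded (< minimum size) or unresolvable communities
#' receive the reserved leaf id 0 so downstream accounting is conserved.
#'
#' @param tree a `CommunityTree` from [hierarchical_detect()].
#' @param path output path (TSV).
#' @return the written data frame, invisibly.
#' @export
write_partition <- function(tree, path) {
  df <- partition_table(tree)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a serialized community partition
#'
#' @param path a file written by [write_partition()].
#' @return data frame with columns `gene_id`, `level_*` and `leaf_id`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene in partition file")
  df$gene_id <- as.character(df$gene_id)
  df
}

#' Tabulate a community tree
#'
#' @param tree a `CommunityTree`.
#' @return data frame with `gene_id`, one `level_<d>` column per hierarchy
#'   depth, and `leaf_id` (0 = unassigned).
#' @export
partition_table <- function(tree) {
  stopifnot(inherits(tree, "CommunityTree"))
  leaves <- community_leaves(tree)
  depth <- max(1L, tree$max_depth)
  genes <- tree$root_genes
  path_mat <- matrix(NA_integer_, nrow = length(genes), ncol = depth,
                     dimnames = list(genes, paste0("level_", seq_len(depth))))
  for (g in genes) {
    p <- tree$paths[[g]]
    if (length(p)) path_mat[g, seq_along(p)] <- p
  }
  leaf_id <- stats::setNames(integer(length(genes)), genes)  # default 0
  for (k in seq_along(leaves)) leaf_id[leaves[[k]]] <- k
  df <- data.frame(gene_id = genes, path_mat, leaf_id = as.integer(leaf_id),
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
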