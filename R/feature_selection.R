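#' Boruta settings
#'
#' @param max_iterations maximum shadow-competition iterations.
#' @param alpha significance level of the binomial hit tests.
#' @param correction multiplicity correction over the feature pool,
#'   `"bonferroni"` (default) or `"none"`.
#' @param rf_trees trees of the internal random forest.
#' @param seed integer seed.
#' @return a `BorutaConfig` list.
#' @export
boruta_config <- function(max_iterations = 100, alpha = 0.05,
                          correction = c("bonferroni", "none"),
                          rf_trees = 300, seed = 1L) {
  stopifnot(max_iterations >= 1, alpha > 0, alpha < 1, rf_trees >= 1)
  structure(list(max_iterations = max_iterations, alpha = alpha,
                 correction = match.arg(correction), rf_trees = rf_trees,
                 seed = as.integer(seed)),
            class = "BorutaConfig")
}

#' Shadow features: per-column permutations
#'
#' One shadow per feature, obtained by permuting that feature's values
#' across samples independently per feature; each shadow column is
#' multiset-equal to its source column but carries no association with the
#' outcome.
#'
#' @param X samples x features numeric matrix.
#' @param seed integer seed.
#' @return matrix of the same shape with columns named `shadow_<original>`.
#' @export
make_shadow_features <- function(X, seed = 1L) {
  stopifnot(is.matrix(X), ncol(X) >= 1)
  with_seed(seed, {
    S <- apply(X, 2, function(col) col[sample.int(length(col))])
  })
  colnames(S) <- paste0("shadow_", colnames(X) %||% seq_len(ncol(X)))
  S
}

#' All-relevant feature selection by shadow competition (Boruta)
#'
#' Iteratively extends the candidate pool with fresh shadow features,
#' trains a random forest, and scores a "hit" for every real feature whose
#' out-of-bag permutation importance exceeds the maximum shadow importance.
#' After each iteration a binomial test of the hit count against
#' Binomial(n_iter, 0.5) at the (Bonferroni-corrected) `alpha` confirms
#' upper-tail features and rejects lower-tail ones; rejected features leave
#' the pool. Stops when nothing is tentative or `max_iterations` is
#' reached.
#'
#' @param X samples x features numeric matrix (feature names required).
#' @param y two-level factor (or coercible) of sample classes.
#' @param cfg a [boruta_config()].
#' @return a `BorutaResult` list: `status` (named: confirmed / rejected /
#'   tentative), `hit_counts`, `n_iterations_run`, `importance_history`
#'   (per-iteration list with feature and shadow importances), `selected`
#'   (the confirmed feature names).
#' @export
boruta_select <- function(X, y, cfg = boruta_config()) {
  stopifnot(is.matrix(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (min(table(y)) < 2) stop("need >= 2 samples per class")

  features <- colnames(X)
  status <- stats::setNames(rep("tentative", length(features)), features)
  hits <- stats::setNames(integer(length(features)), features)
  history <- list()
  n_iter <- 0L
  alpha_adj <- if (cfg$correction == "bonferroni") {
    cfg$alpha / length(features)
  } else {
    cfg$alpha
  }

  for (iter in seq_len(cfg$max_iterations)) {
    pool <- features[status[features] != "rejected"]
    if (!length(pool)) break
    n_iter <- iter
    iseed <- derive_seed(cfg$seed, iter)
    Xp <- X[, pool, drop = FALSE]
    shadows <- make_shadow_features(Xp, seed = derive_seed(iseed, 1))
    rf <- with_seed(derive_seed(iseed, 2),
                    randomForest::randomForest(
                      x = cbind(Xp, shadows), y = y,
                      ntree = cfg$rf_trees, importance = TRUE))
    imp <- randomForest::importance(rf, type = 1)[, 1]
    feat_imp <- imp[pool]
    shadow_imp <- imp[colnames(shadows)]
    thr <- max(shadow_imp)
    hits[pool[feat_imp > thr]] <- hits[pool[feat_imp > thr]] + 1L
    history[[iter]] <- list(feature = feat_imp, shadow = shadow_imp)

    tent <- names(status)[status == "tentative"]
    p_up <- pbinom(hits[tent] - 1, iter, 0.5, lower.tail = FALSE)
    p_dn <- pbinom(hits[tent], iter, 0.5)
    status[tent[p_up < alpha_adj]] <- "confirmed"
    status[tent[p_dn < alpha_adj]] <- "rejected"
    if (!any(status == "tentative")) break
  }

  structure(
    list(status = status, hit_counts = hits, n_iterations_run = n_iter,
         importance_history = history,
         selected = names(status)[status == "confirmed"]),
    class = "BorutaResult"
  )
}

#' @export
print.BorutaResult <- function(x, ...) {
  tab <- table(factor(x$status, c("confirmed", "tentative", "rejected")))
  cat(sprintf("BorutaResult after %d iteration(s): %d confirmed, %d tentative, %d rejected\n",
              x$n_iterations_run, tab["confirmed"], tab["tentative"],
              tab["rejected"]))
  invisible(x)
}

#' Split configuration for the selection/classification partition
#'
#' @param selection_fraction fraction of samples reserved for feature
#'   selection (default 0.40; the remainder goes to classification).
#' @param stratified keep class proportions in both parts.
#' @param seed integer seed.
#' @return a `SplitConfig` list.
#' @export
split_config <- function(selection_fraction = 0.40, stratified = TRUE,
                         seed = 1L) {
  stopifnot(selection_fraction > 0, selection_fraction < 1)
  structure(list(selection_fraction = selection_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "SplitConfig")
}

#' Partition samples into a selection set and a classification set
#'
#' The selection set (default 40% of samples) is used for feature
#' selection only, the disjoint remainder for classifier training and
#' cross-validation, so selection never sees classification labels.
#' Per-class sizes are rounded to the nearest integer (clamped so both
#' parts retain at least one sample per class).
#'
#' @param sample_ids character vector of sample ids.
#' @param labels named character vector covering `sample_ids`.
#' @param cfg a [split_config()].
#' @return list with character vectors `selection` and `classification`
#'   (disjoint, union = `sample_ids`).
#' @export
split_selection_classification <- function(sample_ids, labels,
                                           cfg = split_config()) {
  labels <- labels[sample_ids]
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")
  sel <- character(0)
  with_seed(cfg$seed, {
    if (cfg$stratified) {
      for (cl in unique(labels)) {
        ids <- sample_ids[labels == cl]
        k <- round(cfg$selection_fraction * length(ids))
        k <- min(max(k, 1L), length(ids) - 1L)
        sel <- c(sel, sample(ids, k))
      }
    } else {
      k <- round(cfg$selection_fraction * length(sample_ids))
      k <- min(max(k, 1L), length(sample_ids) - 1L)
      sel <- sample(sample_ids, k)
    }
  })
  sel <- sample_ids[sample_ids %in% sel]  # preserve input order
  list(selection = sel,
       classification = setdiff(sample_ids, sel))
}
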