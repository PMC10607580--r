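#' Random-forest settings
#'
#' @param n_trees number of bootstrap-grown CART trees (M).
#' @param mtry `"all_features"` (default: every feature is a split
#'   candidate, i.e. bagged trees, s = |S|) or `"sqrt"`.
#' @param seed integer seed.
#' @return an `RFConfig` list.
#' @export
rf_config <- function(n_trees = 300, mtry = c("all_features", "sqrt"),
                      seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = n_trees, mtry = match.arg(mtry),
                 seed = as.integer(seed)),
            class = "RFConfig")
}

#' Cross-validation settings
#'
#' @param k_folds folds per round (>= 2).
#' @param repeats number of repeated rounds, each with a fresh random
#'   split.
#' @param stratified stratify folds by class.
#' @param seed integer seed.
#' @return a `CVConfig` list.
#' @export
cv_config <- function(k_folds = 5, repeats = 100, stratified = TRUE,
                      seed = 1L) {
  stopifnot(k_folds >= 2, repeats >= 1)
  structure(list(k_folds = k_folds, repeats = repeats,
                 stratified = stratified, seed = as.integer(seed)),
            class = "CVConfig")
}

#' Train a random-forest classifier
#'
#' Bootstrap ensemble of CART trees via the randomForest package;
#' probability output is the tree-vote fraction. Deterministic given
#' `cfg$seed`.
#'
#' @param X samples x features numeric matrix.
#' @param y two-level factor; the positive class is given by `positive`.
#' @param cfg an [rf_config()].
#' @param positive name of the positive class (default `"tumor"` if
#'   present, else the second factor level).
#' @return an `rf_model` wrapper holding the forest, feature names,
#'   training feature means (for missing-gene imputation in external
#'   validation) and the positive class.
#' @export
train_rf <- function(X, y, cfg = rf_config(), positive = NULL) {
  stopifnot(is.matrix(X))
  if (ncol(X) < 1) stop("no features to train on")
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (min(table(y)) < 1) stop("need samples of both classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  positive <- positive %||% if ("tumor" %in% levels(y)) "tumor" else levels(y)[2]
  if (!positive %in% levels(y)) stop("positive class not a level of y")
  mtry <- switch(cfg$mtry,
                 all_features = ncol(X),
                 sqrt = max(1, floor(sqrt(ncol(X)))))
  fit <- with_seed(cfg$seed,
                   randomForest::randomForest(x = X, y = y,
                                              ntree = cfg$n_trees,
                                              mtry = mtry))
  structure(
    list(forest = fit, features = colnames(X),
         feature_means = colMeans(X), positive = positive,
         levels = levels(y)),
    class = "rf_model"
  )
}

#' Predict positive-class probabilities
#'
#' @param model an `rf_model` from [train_rf()].
#' @param X samples x features matrix containing the model's features.
#' @return numeric vector of tree-vote fractions for the positive class.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "rf_model"))
  X <- X[, model$features, drop = FALSE]
  as.numeric(predict(model$forest, X, type = "prob")[, model$positive])
}

#' Binary classification metrics
#'
#' Accuracy, AUC and F1 are reported as percentages; log loss on the
#' natural-log scale. AUC uses the rank (pair-counting) definition with
#' half credit for ties; F1 is computed for the positive class, with the
#' convention F1 = 0 when there are no true positives. Probabilities are
#' clipped to `[1e-15, 1 - 1e-15]` for the log loss.
#'
#' @param y_true 0/1 vector (1 = positive class).
#' @param y_prob predicted positive-class probabilities.
#' @param threshold decision threshold for accuracy/F1 (predict positive
#'   when `y_prob > threshold`).
#' @return a `MetricSet` list: `accuracy`, `auc`, `f1` (percent),
#'   `logloss`.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob))
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2) {
    stop("AUC undefined: y_true contains a single class")
  }
  pred <- as.integer(y_prob > threshold)
  acc <- 100 * mean(pred == y_true)
  # rank-based AUC (equivalent to pair counting with tie half-credit)
  r <- rank(y_prob)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  auc <- 100 * (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  f1 <- if (tp == 0) 0 else 100 * 2 * tp / (2 * tp + fp + fn)
  p <- pmin(pmax(y_prob, 1e-15), 1 - 1e-15)
  ll <- -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  structure(list(accuracy = acc, auc = auc, f1 = f1, logloss = ll),
            class = "MetricSet")
}

stratified_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation of a random forest
#'
#' For each repeat a fresh stratified fold split of the samples is drawn;
#' per fold the forest is trained on the remaining folds and scores the
#' held-out fold. The held-out predictions of one repeat are pooled into a
#' single [compute_metrics()] evaluation, and metrics are summarized as
#' mean and SD over repeats. Folds always split samples, never genes.
#'
#' @param X samples x features matrix.
#' @param y two-level factor.
#' @param rf an [rf_config()].
#' @param cv a [cv_config()].
#' @param positive positive class passed to [train_rf()].
#' @return a `CVReport` list: `rounds` (data frame, one row per repeat),
#'   `summary` (mean and sd per metric), `config` echo.
#' @export
repeated_cv <- function(X, y, rf = rf_config(), cv = cv_config(),
                        positive = NULL) {
  stopifnot(is.matrix(X))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (cv$stratified && cv$k_folds > min(table(y))) {
    stop("k_folds exceeds the smallest class count; stratification infeasible")
  }
  positive <- positive %||% if ("tumor" %in% levels(y)) "tumor" else levels(y)[2]
  y_bin <- as.integer(y == positive)
  rounds <- vector("list", cv$repeats)
  for (r in seq_len(cv$repeats)) {
    fold <- stratified_folds(y, cv$k_folds, derive_seed(cv$seed, "fold", r),
                             cv$stratified)
    prob <- rep(NA_real_, length(y))
    for (f in seq_len(cv$k_folds)) {
      train <- fold != f
      cfg_f <- rf
      cfg_f$seed <- derive_seed(rf$seed, "rf", r, f)
      model <- train_rf(X[train, , drop = FALSE], y[train], cfg_f,
                        positive = positive)
      prob[!train] <- predict_prob(model, X[!train, , drop = FALSE])
    }
    ms <- compute_metrics(y_bin, prob)
    rounds[[r]] <- data.frame(repeat_id = r, accuracy = ms$accuracy,
                              auc = ms$auc, f1 = ms$f1, logloss = ms$logloss)
  }
  rounds <- do.call(rbind, rounds)
  metr <- c("accuracy", "auc", "f1", "logloss")
  structure(
    list(rounds = rounds,
         summary = data.frame(
           metric = metr,
           mean = vapply(rounds[metr], mean, numeric(1)),
           sd = vapply(rounds[metr], sd, numeric(1))),
         config = list(rf = rf, cv = cv, positive = positive)),
    class = "CVReport"
  )
}

#' @export
print.CVReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CVReport over %d repeats: %s\n", nrow(x$rounds),
              paste(sprintf("%s %.2f +/- %.2f", s$metric, s$mean, s$sd),
                    collapse = ", ")))
  invisible(x)
}

#' Rank communities by cross-validated accuracy
#'
#' @param reports named list of `CVReport`s, one per community.
#' @param accuracy_cutoff retain communities whose mean CV accuracy
#'   strictly exceeds this percentage (default 90).
#' @return character vector of community names, sorted by descending mean
#'   accuracy.
#' @export
rank_communities <- function(reports, accuracy_cutoff = 90) {
  if (!length(reports)) return(character(0))
  acc <- vapply(reports, function(r)
    r$summary$mean[r$summary$metric == "accuracy"], numeric(1))
  keep <- acc > accuracy_cutoff
  names(sort(acc[keep], decreasing = TRUE))
}

#' Validate a trained model on an external expression dataset
#'
#' Features are matched by gene identifier; genes absent from the test
#' matrix are imputed at their training-set mean (with a warning carrying
#' the imputation count). A single point estimate per metric is returned
#' (no cross-validation).
#'
#' @param model an `rf_model` from [train_rf()].
#' @param test_matrix an [expression_matrix()] with labels.
#' @param positive positive class in the test labels (default: the
#'   model's).
#' @return a `MetricSet` with attribute `"n_imputed"`.
#' @export
external_validate <- function(model, test_matrix, positive = NULL) {
  stopifnot(inherits(model, "rf_model"),
            inherits(test_matrix, "ExpressionMatrix"))
  if (is.null(test_matrix$labels)) stop("test matrix carries no labels")
  positive <- positive %||% model$positive
  present <- intersect(model$features, test_matrix$gene_ids)
  if (!length(present)) stop("no overlapping genes between model and test set")
  missing <- setdiff(model$features, present)
  n <- length(test_matrix$sample_ids)
  X <- matrix(rep(model$feature_means, each = n), nrow = n,
              dimnames = list(test_matrix$sample_ids, model$features))
  X[, present] <- t(test_matrix$values[present, , drop = FALSE])
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from the test matrix; ",
            "imputed at training means")
  }
  y_bin <- as.integer(test_matrix$labels == positive)
  out <- compute_metrics(y_bin, predict_prob(model, X))
  attr(out, "n_imputed") <- length(missing)
  out
}
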