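# Shapley-value attribution for community classifiers.
#
# The value function for a feature subset F is the interventional
# expectation: the model's mean prediction over a fixed background sample
# collection with the features in F pinned to the explained sample's
# values. Retraining the model on every feature subset is computationally
# prohibitive; the interventional expectation is the accepted surrogate and
# is used consistently by both the exact enumerator and the permutation
# estimator, so the two converge to the same attributions.

value_fn <- function(model) {
  if (inherits(model, "rf_model")) {
    function(X) predict_prob(model, X)
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be an rf_model or a prediction function")
  }
}

#' Exact Shapley values by subset enumeration
#'
#' Evaluates the Shapley sum over all feature subsets with the factorial
#' weights `|F|! (|S|-|F|-1)! / |S|!`, using the interventional value
#' function over `background`. Exponential in the feature count, so capped
#' at `max_features`.
#'
#' @param model an `rf_model` or a function mapping a samples x features
#'   matrix to a numeric prediction vector.
#' @param x named numeric vector: the sample to explain.
#' @param background matrix of background samples (columns = features of
#'   `x`).
#' @param max_features enumeration bound (default 15).
#' @return named numeric vector of Shapley values, with attribute
#'   `"base_value"` (mean background prediction).
#' @export
exact_shap <- function(model, x, background, max_features = 15) {
  f <- value_fn(model)
  feats <- names(x)
  if (is.null(feats)) stop("x must be a named feature vector")
  p <- length(feats)
  if (p > max_features) {
    stop("more than ", max_features,
         " features; use approx_shap() for large feature sets")
  }
  background <- background[, feats, drop = FALSE]
  B <- nrow(background)
  n_mask <- bitwShiftL(1L, p)
  # value of every subset in one batched prediction
  big <- matrix(0, nrow = n_mask * B, ncol = p, dimnames = list(NULL, feats))
  for (mask in 0:(n_mask - 1)) {
    M <- background
    for (j in seq_len(p)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) M[, j] <- x[j]
    }
    big[(mask * B + 1):((mask + 1) * B), ] <- M
  }
  pred <- f(big)
  v <- vapply(0:(n_mask - 1),
              function(mask) mean(pred[(mask * B + 1):((mask + 1) * B)]),
              numeric(1))
  wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
               lfactorial(p))
  sizes <- vapply(0:(n_mask - 1), function(mask) sum(
    bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L), integer(1))
  phi <- stats::setNames(numeric(p), feats)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_mask - 1), bit) == 0L) - 1L
    fsize <- sizes[without + 1L]
    phi[j] <- sum(wts[fsize + 1] * (v[without + bit + 1L] - v[without + 1L]))
  }
  attr(phi, "base_value") <- v[1]
  phi
}

#' Permutation-sampling Shapley estimates
#'
#' Monte-Carlo estimate of the Shapley values: random feature orderings are
#' drawn, and each feature is credited with the change in the
#' interventional value when it is added to its predecessors. Converges to
#' [exact_shap()] as `n_permutations` grows; the local-accuracy identity
#' `base + sum(shap) = f(x)` holds exactly at any `n_permutations` because
#' each ordering's contributions telescope.
#'
#' @param model an `rf_model` or prediction function.
#' @param X_explain samples x features matrix of samples to explain.
#' @param background background sample matrix (same features).
#' @param n_permutations orderings per explained sample (>= 1).
#' @param seed integer seed.
#' @return a `ShapExplanation` list: `base_value`, `shap_values`
#'   (samples x features), `feature_values` (= `X_explain`),
#'   `prediction` (f on `X_explain`).
#' @export
approx_shap <- function(model, X_explain, background, n_permutations = 200,
                        seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  f <- value_fn(model)
  X_explain <- as.matrix(X_explain)
  feats <- colnames(X_explain)
  if (is.null(feats)) stop("X_explain must have feature column names")
  background <- background[, feats, drop = FALSE]
  B <- nrow(background)
  p <- length(feats)
  base <- mean(f(background))
  fx <- f(X_explain)
  shap <- matrix(0, nrow = nrow(X_explain), ncol = p,
                 dimnames = list(rownames(X_explain), feats))

  chunk <- max(1L, floor(20000 / max(1L, (p - 1) * B)))
  for (s in seq_len(nrow(X_explain))) {
    x <- X_explain[s, ]
    orders <- with_seed(derive_seed(seed, "perm", s), {
      lapply(seq_len(n_permutations), function(i) sample.int(p))
    })
    phi <- stats::setNames(numeric(p), feats)
    done <- 0L
    while (done < n_permutations) {
      take <- orders[seq(done + 1L, min(done + chunk, n_permutations))]
      if (p > 1) {
        rows <- length(take) * (p - 1) * B
        big <- matrix(0, nrow = rows, ncol = p,
                      dimnames = list(NULL, feats))
        at <- 0L
        for (o in take) {
          M <- background
          for (k in seq_len(p - 1)) {
            M[, o[k]] <- x[o[k]]
            big[(at + 1):(at + B), ] <- M
            at <- at + B
          }
        }
        pred <- f(big)
        at <- 0L
        for (o in take) {
          v_prev <- base
          for (k in seq_len(p - 1)) {
            v_k <- mean(pred[(at + 1):(at + B)])
            phi[o[k]] <- phi[o[k]] + (v_k - v_prev)
            v_prev <- v_k
            at <- at + B
          }
          phi[o[p]] <- phi[o[p]] + (fx[s] - v_prev)
        }
      } else {
        phi[1] <- phi[1] + length(take) * (fx[s] - base)
      }
      done <- done + length(take)
    }
    shap[s, ] <- phi / n_permutations
  }
  structure(
    list(base_value = base, shap_values = shap,
         feature_values = X_explain, prediction = fx),
    class = "ShapExplanation"
  )
}

#' Summarize a Shapley explanation
#'
#' Features are ranked by mean absolute Shapley value; each feature's
#' direction is the sign of the correlation between its value and its
#' Shapley value across the explained samples (positive means higher
#' expression pushes predictions toward the positive/tumor class).
#'
#' @param exp a `ShapExplanation` from [approx_shap()].
#' @param top_k how many leading features to flag (clamped to the feature
#'   count).
#' @return a `ShapSummary` list: `ranking` (data frame over all features:
#'   `feature`, `mean_abs_shap`, `direction`), `top` (leading feature
#'   names).
#' @export
shap_summary <- function(exp, top_k = 20) {
  stopifnot(inherits(exp, "ShapExplanation"), nrow(exp$shap_values) >= 1)
  mas <- colMeans(abs(exp$shap_values))
  dir <- vapply(seq_along(mas), function(j) {
    sv <- exp$shap_values[, j]
    fv <- exp$feature_values[, j]
    if (sd(sv) == 0 || sd(fv) == 0) return(0)
    sign(cor(fv, sv))
  }, numeric(1))
  ord <- order(mas, decreasing = TRUE)
  ranking <- data.frame(feature = colnames(exp$shap_values)[ord],
                        mean_abs_shap = as.numeric(mas[ord]),
                        direction = as.numeric(dir[ord]),
                        stringsAsFactors = FALSE)
  structure(
    list(ranking = ranking,
         top = head(ranking$feature, min(top_k, nrow(ranking)))),
    class = "ShapSummary"
  )
}

#' Local-accuracy check of an explanation
#'
#' @param exp a `ShapExplanation`.
#' @return maximum absolute deviation of `base + sum(shap)` from the model
#'   prediction over the explained samples.
#' @export
shap_local_accuracy <- function(exp) {
  stopifnot(inherits(exp, "ShapExplanation"))
  max(abs(exp$base_value + rowSums(exp$shap_values) - exp$prediction))
}
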