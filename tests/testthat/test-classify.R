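test_that("metrics reproduce hand-enumerated values", {
  # pair counting: 3 concordant pairs + 1 tie at 0.4 -> AUC 3.5/4
  ms <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.4, 0.1))
  expect_equal(ms$accuracy, 75)
  expect_equal(ms$auc, 87.5)
  expect_equal(ms$f1, 100 * 2 / 3, tolerance = 1e-12)

  perfect <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$auc, 100)
  expect_equal(perfect$f1, 100)
  expect_lt(perfect$logloss, 1e-10)

  # constant 0.5 probabilities: log loss is ln 2
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))$logloss, log(2))

  expect_error(compute_metrics(c(1, 1), c(0.2, 0.8)), "single class")
})

test_that("rank-based AUC equals brute-force pair counting", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), 2)  # rounding forces frequent ties
    expect_equal(compute_metrics(y, p)$auc, auc_oracle(y, p),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to sample order", {
  set.seed(6)
  y <- sample(0:1, 30, replace = TRUE)
  y[1:2] <- c(0, 1)
  p <- runif(30)
  perm <- sample(30)
  a <- compute_metrics(y, p)
  b <- compute_metrics(y[perm], p[perm])
  expect_equal(unclass(a), unclass(b))
})

test_that("random forests separate planted structure deterministically", {
  set.seed(7)
  n <- 80
  y <- factor(rep(c("tumor", "normal"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[y == "tumor", 1] <- X[y == "tumor", 1] + 4
  model <- train_rf(X, y, rf_config(seed = 8))
  expect_gte(mean((predict_prob(model, X) > 0.5) ==
                    (y == "tumor")), 0.95)
  expect_identical(predict_prob(model, X),
                   predict_prob(train_rf(X, y, rf_config(seed = 8)), X))
  expect_error(train_rf(X, factor(rep("tumor", n))), "two classes")
})

test_that("repeated CV pools held-out folds and is calibrated on noise", {
  set.seed(9)
  n <- 60
  y <- factor(rep(c("tumor", "normal"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  X[y == "tumor", 1:4] <- X[y == "tumor", 1:4] + 3
  rep1 <- repeated_cv(X, y, rf_config(n_trees = 100, seed = 1),
                      cv_config(repeats = 4, seed = 2))
  expect_equal(nrow(rep1$rounds), 4)
  expect_gte(rep1$summary$mean[rep1$summary$metric == "accuracy"], 90)
  # distinct splits give non-degenerate spread
  expect_true(any(rep1$summary$sd > 0))
  # determinism of the full report
  rep2 <- repeated_cv(X, y, rf_config(n_trees = 100, seed = 1),
                      cv_config(repeats = 4, seed = 2))
  expect_identical(rep1$rounds, rep2$rounds)

  # pure-noise features: pooled AUC near 50
  Xn <- matrix(rnorm(120 * 10), 120, 10,
               dimnames = list(NULL, paste0("f", 1:10)))
  yn <- factor(rep(c("tumor", "normal"), each = 60))
  repn <- repeated_cv(Xn, yn, rf_config(n_trees = 100, seed = 3),
                      cv_config(repeats = 4, seed = 4))
  aucn <- repn$summary$mean[repn$summary$metric == "auc"]
  expect_gt(aucn, 38)
  expect_lt(aucn, 62)

  expect_error(repeated_cv(X[1:8, ], y[c(1:4, 31:34)],
                           cv = cv_config(k_folds = 5)),
               "stratification")
})

test_that("each repeat's folds cover every sample exactly once", {
  y <- factor(rep(c("a", "b"), each = 25))
  for (s in 1:5) {
    fold <- coexcomm:::stratified_folds(y, 5, seed = s)
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(length(fold), 50)
    # stratification: each fold has 5 of each class
    expect_true(all(table(fold, y) == 5))
  }
})

test_that("community ranking filters and orders by mean accuracy", {
  fake_report <- function(acc) {
    structure(list(summary = data.frame(metric = "accuracy", mean = acc,
                                        sd = 1)),
              class = "CVReport")
  }
  reports <- list(a = fake_report(95), b = fake_report(89),
                  c = fake_report(91))
  expect_equal(rank_communities(reports, 90), c("a", "c"))
  expect_equal(rank_communities(reports, 0), c("a", "c", "b"))
  expect_equal(rank_communities(list(), 90), character(0))
})

test_that("external validation matches genes and imputes what is missing", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 80, normal = 80),
                        module_sizes = 30, n_noise_genes = 10,
                        discriminative_flags = TRUE, effect_size = 3,
                        seed = 21)
  train <- generate_dataset(d)
  test <- generate_dataset(synthetic_design(
    n_samples_per_class = c(tumor = 60, normal = 60), module_sizes = 30,
    n_noise_genes = 10, discriminative_flags = TRUE, effect_size = 3,
    seed = 22))
  genes <- train$matrix$gene_ids[1:30]
  X <- t(train$matrix$values[genes, ])
  y <- factor(train$matrix$labels)
  model <- train_rf(X, y, rf_config(seed = 5))
  cv <- repeated_cv(X, y, rf_config(seed = 5), cv_config(repeats = 3, seed = 6))

  ms <- external_validate(model, test$matrix)
  # same generative law: external accuracy close to the training CV mean
  expect_lt(abs(ms$accuracy - cv$summary$mean[cv$summary$metric == "accuracy"]),
            7)
  expect_equal(attr(ms, "n_imputed"), 0)

  # drop half the genes from the test set: imputation count matches
  half <- subset_expression(test$matrix, genes = test$matrix$gene_ids[16:40])
  expect_warning(ms2 <- external_validate(model, half), "imputed")
  expect_equal(attr(ms2, "n_imputed"), 15)

  # permuted labels: AUC near chance
  set.seed(23)
  perm <- test$matrix
  perm$labels <- setNames(sample(perm$labels), names(perm$labels))
  msp <- external_validate(model, perm)
  expect_gt(msp$auc, 38)
  expect_lt(msp$auc, 62)

  none <- subset_expression(test$matrix, genes = test$matrix$gene_ids[31:40])
  expect_error(external_validate(model, none), "no overlapping genes")
})

test_that("feature selection never sees classification labels", {
  ids <- sprintf("s%03d", 1:60)
  labels <- setNames(rep(c("tumor", "normal"), each = 30), ids)
  sp <- split_selection_classification(ids, labels, split_config(seed = 3))
  # the two sample sets flowing into boruta_select and repeated_cv are disjoint
  expect_length(intersect(sp$selection, sp$classification), 0)
  expect_setequal(union(sp$selection, sp$classification), ids)
})
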