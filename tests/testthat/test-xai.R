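# A deterministic linear "model" gives closed-form Shapley values to test
# against; random forests exercise the batched prediction path.

linear_fn <- function(coefs) {
  function(X) as.numeric(X[, names(coefs), drop = FALSE] %*% coefs)
}

test_that("a single feature gets the full deviation from the background mean", {
  f <- linear_fn(c(x1 = 2))
  bg <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x1"))
  x <- c(x1 = 1.7)
  phi <- exact_shap(f, x, bg)
  expect_equal(unname(phi["x1"]), 2 * (1.7 - mean(bg[, 1])), tolerance = 1e-12)
  expect_equal(attr(phi, "base_value"), mean(f(bg)), tolerance = 1e-12)
})

test_that("linear models have closed-form Shapley values", {
  set.seed(1)
  f <- linear_fn(c(x1 = 1.5, x2 = -3, x3 = 0.25))
  bg <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  x <- c(x1 = 0.4, x2 = -1.2, x3 = 2)
  phi <- exact_shap(f, x, bg)
  expect_equal(as.numeric(phi),
               unname(c(1.5, -3, 0.25) * (x - colMeans(bg))),
               tolerance = 1e-10)
})

test_that("symmetry and dummy axioms hold on constructed toys", {
  # duplicate features: f depends on the sum, both get equal credit
  f <- function(X) X[, "a"] + X[, "b"]
  set.seed(2)
  v <- rnorm(25)
  bg <- cbind(a = v, b = v, c = rnorm(25))
  phi <- exact_shap(f, c(a = 1, b = 1, c = 5), bg)
  expect_equal(phi[["a"]], phi[["b"]], tolerance = 1e-10)
  # ignored feature gets exactly zero
  expect_equal(phi[["c"]], 0)
})

test_that("enumeration bound is enforced and constant models explain to zero", {
  bg <- matrix(0, 4, 16, dimnames = list(NULL, paste0("f", 1:16)))
  x <- setNames(rep(1, 16), paste0("f", 1:16))
  expect_error(exact_shap(function(X) rep(1, nrow(X)), x, bg), "approx_shap")

  bgc <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Xe <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("f", 1:4)))
  exp0 <- approx_shap(function(X) rep(0.3, nrow(X)), Xe, bgc,
                      n_permutations = 5, seed = 1)
  expect_equal(max(abs(exp0$shap_values)), 0)
  expect_error(approx_shap(function(X) rep(1, nrow(X)), Xe, bgc,
                           n_permutations = 0), "n_permutations")
})

test_that("local accuracy holds at any permutation count", {
  set.seed(3)
  n <- 60
  y <- factor(rep(c("tumor", "normal"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[y == "tumor", 1] <- X[y == "tumor", 1] + 2
  model <- train_rf(X, y, rf_config(n_trees = 80, seed = 4))
  bg <- X[1:15, ]
  Xe <- X[41:45, ]
  for (np in c(1, 10, 50)) {
    exp <- approx_shap(model, Xe, bg, n_permutations = np, seed = 5)
    expect_lt(shap_local_accuracy(exp), 1e-6)
  }
})

test_that("the permutation estimator converges to the enumeration oracle", {
  set.seed(6)
  n <- 80
  y <- factor(rep(c("tumor", "normal"), each = n / 2))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[y == "tumor", 1:2] <- X[y == "tumor", 1:2] + 2
  model <- train_rf(X, y, rf_config(n_trees = 60, seed = 7))
  bg <- X[seq(1, 80, by = 8), ]
  xe <- X[44, , drop = FALSE]
  exact <- exact_shap(model, X[44, ], bg)

  errs <- vapply(c(10, 100, 1000), function(np) {
    ap <- approx_shap(model, xe, bg, n_permutations = np, seed = 8)
    median(abs(ap$shap_values[1, ] - exact))
  }, numeric(1))
  # median error non-increasing across 10 -> 100 -> 1000 permutations
  expect_true(all(diff(errs) <= 1e-3))
  expect_lt(errs[3], 0.02)
})

test_that("shap summaries rank planted effects and flag directions", {
  set.seed(9)
  n <- 150
  y <- factor(rep(c("tumor", "normal"), each = n / 2))
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("strong", "weak", "null1", "null2")))
  X[y == "tumor", "strong"] <- X[y == "tumor", "strong"] + 3
  X[y == "tumor", "weak"] <- X[y == "tumor", "weak"] + 1
  model <- train_rf(X, y, rf_config(n_trees = 150, seed = 10))
  exp <- approx_shap(model, X[seq(1, n, by = 5), ], X[seq(2, n, by = 5), ],
                     n_permutations = 60, seed = 11)
  summ <- shap_summary(exp, top_k = 2)
  expect_equal(summ$ranking$feature[1], "strong")
  expect_equal(summ$ranking$feature[2], "weak")
  expect_length(summ$top, 2)
  # higher expression of the planted markers pushes toward tumor
  expect_equal(summ$ranking$direction[summ$ranking$feature == "strong"], 1)
  expect_setequal(summ$ranking$feature, colnames(X))

  # top_k larger than the feature count returns everything
  expect_length(shap_summary(exp, top_k = 99)$top, 4)

  # a feature with zero attribution everywhere ranks last with direction 0
  exp0 <- exp
  exp0$shap_values[, "null2"] <- 0
  s0 <- shap_summary(exp0)
  expect_equal(s0$ranking$feature[4], "null2")
  expect_equal(s0$ranking$direction[4], 0)
})
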