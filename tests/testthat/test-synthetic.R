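test_that("generation is deterministic and conserves the planted truth", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 30, normal = 30),
                        module_sizes = c(20, 15), n_noise_genes = 10,
                        seed = 5)
  a <- generate_dataset(d)
  b <- generate_dataset(d)
  expect_identical(a$matrix$values, b$matrix$values)
  # every gene has exactly one planted module id; dims are consistent
  expect_length(a$truth$gene_module, nrow(a$matrix$values))
  expect_setequal(names(a$truth$gene_module), a$matrix$gene_ids)
  expect_equal(sum(a$truth$gene_module == 0), 10)
  expect_length(a$truth$sample_class, ncol(a$matrix$values))
})

test_that("within-module sample correlation matches the closed form", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 100, normal = 100),
                        module_sizes = 50, n_noise_genes = 0,
                        discriminative_flags = FALSE, rho_within = 0.8,
                        seed = 2)
  ds <- generate_dataset(d)
  C <- cor(t(ds$matrix$values))
  off <- C[upper.tri(C)]
  # lambda^2/(lambda^2+sigma^2) = 0.8 plus Fisher-z sampling slack at n=200
  expect_gt(mean(off), 0.74)
  expect_lt(mean(off), 0.86)
})

test_that("a zero effect size is null-calibrated for per-gene t-tests", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 60, normal = 60),
                        module_sizes = integer(0), n_noise_genes = 400,
                        discriminative_flags = logical(0), effect_size = 0,
                        seed = 3)
  ds <- generate_dataset(d)
  cls <- ds$matrix$labels
  p <- apply(ds$matrix$values, 1, function(x)
    t.test(x[cls == "tumor"], x[cls == "normal"])$p.value)
  # ~5% of independent null genes exceed the 0.05 critical value
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("nested designs plant the two-level correlation structure", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 100, normal = 100),
                        module_sizes = 150,
                        nesting = list("1" = c(60, 50, 40)),
                        rho_within = 0.8, rho_super = 0.3,
                        n_noise_genes = 0, discriminative_flags = FALSE,
                        seed = 4)
  ds <- generate_nested_dataset(d)
  C <- cor(t(ds$matrix$values))
  sub <- ds$truth$gene_submodule
  within <- C[sub == 1, sub == 1]
  between <- C[sub == 1, sub == 2]
  expect_gt(mean(within[upper.tri(within)]), 0.74)
  expect_lt(mean(within[upper.tri(within)]), 0.86)
  expect_gt(mean(between), 0.24)
  expect_lt(mean(between), 0.36)
  # coarse level: one super-module, fine level: three children
  expect_equal(length(unique(ds$truth$gene_module)), 1)
  expect_equal(length(unique(sub)), 3)
})

test_that("nested generation validates its inputs", {
  d <- synthetic_design(module_sizes = c(60, 50, 40, 30, 20))
  expect_error(generate_nested_dataset(d), "no nesting")
  expect_error(
    synthetic_design(module_sizes = 150, nesting = list("1" = c(60, 50))),
    "sum to 110")
  expect_error(
    synthetic_design(module_sizes = 150, nesting = list("3" = c(150))),
    "not a module index")
})

test_that("two super-modules give a two-block first-level ground truth", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 50, normal = 50),
                        module_sizes = c(150, 120),
                        nesting = list("1" = c(80, 70), "2" = c(60, 60)),
                        n_noise_genes = 10, discriminative_flags = FALSE,
                        seed = 6)
  ds <- generate_nested_dataset(d)
  gm <- ds$truth$gene_module
  expect_setequal(unique(gm), c(0, 1, 2))
  expect_equal(sum(gm == 1), 150)
  expect_equal(sum(gm == 2), 120)
})

test_that("merge-check data draws peritumoral from the normal law", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 40, normal = 150,
                                                peritumoral = 150),
                        peritumoral_shift = 0, seed = 7)
  ds <- generate_merge_check_dataset(d)
  cls <- ds$matrix$labels
  # per-gene means differ only by sampling error under the identical law
  delta <- rowMeans(ds$matrix$values[, cls == "normal"]) -
    rowMeans(ds$matrix$values[, cls == "peritumoral"])
  p <- apply(ds$matrix$values, 1, function(x)
    t.test(x[cls == "normal"], x[cls == "peritumoral"])$p.value)
  expect_lt(mean(abs(delta)), 0.2)
  expect_lt(mean(p < 0.05), 0.12)

  expect_error(generate_merge_check_dataset(
    synthetic_design(n_samples_per_class = c(tumor = 10, normal = 10))),
    "peritumoral")
})

test_that("design validation rejects impossible parameters before sampling", {
  expect_error(synthetic_design(rho_within = 1), "rho_within")
  expect_error(synthetic_design(rho_within = 0), "rho_within")
  expect_error(synthetic_design(n_noise_genes = -1), "non-negative")
  expect_error(synthetic_design(n_samples_per_class = c(bad = 5)), "named")
  expect_error(synthetic_design(noise_sd = 0), "noise_sd")
})
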