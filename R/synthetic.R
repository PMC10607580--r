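#' Describe a synthetic expression study design
#'
#' The generator emulates the structure of a two-cohort liver microarray
#' study: block-correlated gene modules driven by latent factors, a subset
#' of modules whose factor mean shifts between tumor and normal samples, an
#' optional third ("peritumoral") class drawn from the normal generative law
#' plus a small shift, and i.i.d. noise genes. Defaults mirror the study's
#' sample counts (152 tumor, 91 normal-adjacent, 14 peritumoral-adjacent)
#' and a module layout large enough to exercise every downstream stage.
#'
#' Each module m has one latent factor per sample, `z_s ~ N(mu_class, 1)`;
#' gene g in m is `baseline_g + lambda * z_s + eps`, with
#' `lambda = sqrt(rho_within)` and `eps ~ N(0, sqrt(1 - rho_within))` so the
#' model-implied within-module correlation is exactly `rho_within`. The
#' class shift `effect_size` is applied to the factor (not per gene), so all
#' genes of a discriminative module co-shift. Module factors are
#' decorrelated in-sample (orthogonalized before class shifts are applied),
#' so the planted between-module correlation equals its model-implied value
#' exactly rather than drifting by factor-sampling noise; any remaining
#' cross-module correlation is either residual gene noise or genuinely
#' induced by shared class structure.
#'
#' @param n_samples_per_class named integer vector; names from
#'   `c("tumor", "normal", "peritumoral")`.
#' @param module_sizes integer vector of planted module sizes.
#' @param nesting optional named list mapping a module index (as character)
#'   to child module sizes summing to the parent size; used by
#'   [generate_nested_dataset()].
#' @param rho_within target within-module correlation, strictly in (0, 1).
#' @param rho_super shared-factor correlation between children of one
#'   super-module (nested designs only), must be < `rho_within`.
#' @param n_noise_genes number of i.i.d. noise genes.
#' @param discriminative_flags logical per module (recycled); flagged
#'   modules' factors shift by `effect_size` in the tumor class.
#' @param effect_size latent-factor mean shift between classes, in factor
#'   SD units.
#' @param peritumoral_shift factor shift of "peritumoral" relative to
#'   "normal" on discriminative modules (default 0: identical law).
#' @param noise_sd SD of noise-gene expression.
#' @param baseline_mean,baseline_sd per-gene baseline expression level,
#'   emulating a log2 microarray scale.
#' @param global_factor_sd optional weak factor loading shared by all genes
#'   (default 0, i.e. noise genes pairwise independent); nonzero values
#'   stress-test fragmentation handling.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a `SyntheticDesign` list, validated.
#' @export
synthetic_design <- function(n_samples_per_class = c(tumor = 152, normal = 91,
                                                     peritumoral = 14),
                             module_sizes = c(60, 50, 40, 30, 20),
                             nesting = NULL,
                             rho_within = 0.8,
                             rho_super = 0.3,
                             n_noise_genes = 100,
                             discriminative_flags = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                             effect_size = 3,
                             peritumoral_shift = 0,
                             noise_sd = 1,
                             baseline_mean = 7,
                             baseline_sd = 0.5,
                             global_factor_sd = 0,
                             seed = 1L) {
  if (is.null(names(n_samples_per_class)) ||
      !all(names(n_samples_per_class) %in% c("tumor", "normal", "peritumoral"))) {
    stop("n_samples_per_class must be named with tumor/normal/peritumoral")
  }
  if (any(n_samples_per_class < 1)) stop("each class needs at least one sample")
  if (!(rho_within > 0 && rho_within < 1)) {
    stop("rho_within must be strictly between 0 and 1")
  }
  if (length(module_sizes) && any(module_sizes < 1)) stop("module sizes must be positive")
  if (n_noise_genes < 0) stop("n_noise_genes must be non-negative")
  if (effect_size < 0 || peritumoral_shift < 0) stop("effect sizes must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  flags <- rep_len(as.logical(discriminative_flags), length(module_sizes))
  if (!is.null(nesting)) {
    if (!(rho_super > 0 && rho_super < rho_within)) {
      stop("rho_super must lie in (0, rho_within)")
    }
    for (key in names(nesting)) {
      idx <- as.integer(key)
      if (is.na(idx) || idx < 1 || idx > length(module_sizes)) {
        stop("nesting key '", key, "' is not a module index")
      }
      if (sum(nesting[[key]]) != module_sizes[idx]) {
        stop(sprintf("children of module %s sum to %d, expected %d",
                     key, sum(nesting[[key]]), module_sizes[idx]))
      }
    }
  }
  structure(
    list(n_samples_per_class = n_samples_per_class,
         module_sizes = module_sizes, nesting = nesting,
         rho_within = rho_within, rho_super = rho_super,
         n_noise_genes = n_noise_genes, discriminative_flags = flags,
         effect_size = effect_size, peritumoral_shift = peritumoral_shift,
         noise_sd = noise_sd, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, global_factor_sd = global_factor_sd,
         seed = as.integer(seed)),
    class = "SyntheticDesign"
  )
}

sample_classes <- function(design) {
  counts <- design$n_samples_per_class
  cls <- rep(names(counts), counts)
  ids <- sprintf("s%03d", seq_along(cls))
  stats::setNames(cls, ids)
}

factor_mean <- function(class, discriminative, design) {
  if (!discriminative) return(0)
  switch(class,
         tumor = design$effect_size,
         normal = 0,
         peritumoral = design$peritumoral_shift)
}

#' Generate a flat synthetic expression dataset with planted modules
#'
#' @param design a [synthetic_design()] (the `nesting` field is ignored
#'   here; see [generate_nested_dataset()]).
#' @return list with `matrix` (an [expression_matrix()] with labels) and
#'   `truth`: a list with `gene_module` (named integer, 0 = noise gene),
#'   `module_discriminative` (logical per module) and `sample_class`.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  with_seed(design$seed, generate_core(design, nested = FALSE))
}

#' Generate a nested (two-level) synthetic dataset
#'
#' Super-modules listed in `design$nesting` contribute a weak shared factor
#' (between-child correlation `rho_super`) plus strong per-child factors, so
#' the planted hierarchy has a coarse level (the super-modules) and a fine
#' level (their children). At least one super-module should exceed the
#' community-size recursion bound for the hierarchy to be exercised.
#'
#' @param design a [synthetic_design()] with a non-empty `nesting` map.
#' @return as [generate_dataset()], with `truth$gene_submodule` giving the
#'   fine-level planted partition (named integer over all genes, 0 = noise).
#' @export
generate_nested_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  if (is.null(design$nesting) || !length(design$nesting)) {
    stop("design has no nesting map; use generate_dataset() for flat designs")
  }
  with_seed(design$seed, generate_core(design, nested = TRUE))
}

#' Generate the three-class merging-check dataset
#'
#' "Peritumoral" samples are drawn from the normal generative model plus
#' `peritumoral_shift` on the discriminative factors; with shift 0 the two
#' classes are statistically indistinguishable, which is the planted analog
#' of a normal/peritumoral merge in unsupervised clustering.
#'
#' @param design a [synthetic_design()] whose classes include
#'   `"peritumoral"`.
#' @return as [generate_dataset()].
#' @export
generate_merge_check_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  if (!"peritumoral" %in% names(design$n_samples_per_class)) {
    stop("design has no 'peritumoral' class")
  }
  with_seed(design$seed, generate_core(design, nested = FALSE))
}

# Draw k in-sample-orthogonal factors: columns have mean exactly 0, sample
# SD exactly 1, and pairwise sample correlation exactly 0, so the planted
# between-module correlation equals its model-implied value (zero before
# any class shift) instead of drifting by O(1/sqrt(n)) factor-sampling
# noise, which would plant spurious cross-module structure.
orthogonal_factors <- function(n_samp, k) {
  if (k == 0) return(matrix(0, n_samp, 0))
  if (k >= n_samp) stop("need more samples than latent factors")
  Z <- matrix(rnorm(n_samp * k), n_samp, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  qr.Q(qr(Z)) * sqrt(n_samp - 1)
}

generate_core <- function(design, nested) {
  classes <- sample_classes(design)
  n_samp <- length(classes)
  lambda <- sqrt(design$rho_within)
  sigma <- sqrt(1 - design$rho_within)

  sizes <- design$module_sizes
  n_mod_genes <- sum(sizes)
  n_genes <- n_mod_genes + design$n_noise_genes
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  vals <- matrix(0, nrow = n_genes, ncol = n_samp,
                 dimnames = list(gene_ids, names(classes)))

  gene_module <- stats::setNames(integer(n_genes), gene_ids)
  gene_submodule <- stats::setNames(integer(n_genes), gene_ids)
  sub_counter <- 0L

  # one main factor per module, plus one per child of nested modules
  n_children <- if (nested) {
    sum(vapply(design$nesting, length, integer(1)))
  } else {
    0L
  }
  fac <- orthogonal_factors(n_samp, length(sizes) + n_children)
  child_col <- length(sizes)  # child factors live after the module factors

  row <- 0L
  for (m in seq_along(sizes)) {
    disc <- design$discriminative_flags[m]
    mu <- vapply(classes, factor_mean, numeric(1),
                 discriminative = disc, design = design)
    children <- if (nested) design$nesting[[as.character(m)]] else NULL
    if (is.null(children)) {
      z <- fac[, m] + mu
      for (g in seq_len(sizes[m])) {
        row <- row + 1L
        vals[row, ] <- lambda * z + rnorm(n_samp, 0, sigma)
        gene_module[row] <- m
      }
      sub_counter <- sub_counter + 1L
      gene_submodule[gene_module == m] <- sub_counter
    } else {
      # shared weak factor u (between-child corr rho_super) + child factors
      a <- sqrt(design$rho_super)
      b <- sqrt(design$rho_within - design$rho_super)
      sig <- sqrt(1 - design$rho_within)
      u <- fac[, m] + mu
      for (ch in seq_along(children)) {
        sub_counter <- sub_counter + 1L
        child_col <- child_col + 1L
        zc <- fac[, child_col]
        for (g in seq_len(children[ch])) {
          row <- row + 1L
          vals[row, ] <- a * u + b * zc + rnorm(n_samp, 0, sig)
          gene_module[row] <- m
          gene_submodule[row] <- sub_counter
        }
      }
    }
  }
  if (design$n_noise_genes > 0) {
    idx <- (n_mod_genes + 1):n_genes
    vals[idx, ] <- matrix(rnorm(length(idx) * n_samp, 0, design$noise_sd),
                          nrow = length(idx))
  }
  if (design$global_factor_sd > 0) {
    gf <- rnorm(n_samp, 0, 1)
    vals <- vals + design$global_factor_sd *
      matrix(gf, nrow = n_genes, ncol = n_samp, byrow = TRUE)
  }
  baselines <- rnorm(n_genes, design$baseline_mean, design$baseline_sd)
  vals <- vals + baselines

  truth <- list(
    gene_module = gene_module,
    gene_submodule = gene_submodule,
    module_discriminative = stats::setNames(design$discriminative_flags,
                                            seq_along(sizes)),
    sample_class = classes
  )
  list(matrix = expression_matrix(vals, labels = classes), truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression matrix (TSV, genes in rows), the labels (TSV) and
#' the ground truth (JSON) under a common path prefix.
#'
#' @param dataset result of one of the `generate_*` functions.
#' @param prefix path prefix; files `<prefix>_expression.tsv`,
#'   `<prefix>_labels.tsv`, `<prefix>_truth.json` are written.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, prefix) {
  paths <- c(
    expression = paste0(prefix, "_expression.tsv"),
    labels = paste0(prefix, "_labels.tsv"),
    truth = paste0(prefix, "_truth.json")
  )
  write_expression_matrix(dataset$matrix, paths["expression"])
  write_labels(dataset$matrix$labels, paths["labels"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
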