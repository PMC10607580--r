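#' Leiden optimizer settings
#'
#' @param gamma resolution parameter (> 0).
#' @param beta randomness of the refinement phase (> 0).
#' @param n_iterations maximum move/refine/aggregate iterations per run.
#' @param objective quality function; only `"modularity"` (signed two-layer
#'   extension) is supported.
#' @param gamma_grid,beta_grid candidate values scanned by
#'   [select_config()]. Set both to a single value to reproduce a fixed
#'   configuration (e.g. `gamma_grid = 1, beta_grid = 0.05`).
#' @return a `LeidenConfig` list.
#' @export
leiden_config <- function(gamma = 1, beta = 0.05, n_iterations = 200,
                          objective = "modularity",
                          gamma_grid = c(0.5, 0.75, 1.0, 1.25, 1.5),
                          beta_grid = c(0.01, 0.05, 0.1)) {
  stopifnot(gamma > 0, beta > 0, n_iterations >= 1,
            length(gamma_grid) >= 1, length(beta_grid) >= 1)
  objective <- match.arg(objective, "modularity")
  structure(list(gamma = gamma, beta = beta, n_iterations = n_iterations,
                 objective = objective, gamma_grid = gamma_grid,
                 beta_grid = beta_grid),
            class = "LeidenConfig")
}

#' Stability-selection settings
#'
#' @param L number of seeded Leiden runs per configuration.
#' @param nmi_threshold minimum mean pairwise NMI for a majority partition
#'   to count as stable.
#' @param min_fragment_frac a partition is fragmented (and rejected) if any
#'   community is smaller than this fraction of the current (sub)network.
#' @param max_community_size communities at or above this size are recursed
#'   into during hierarchical detection.
#' @param min_community_size communities below this size are discarded.
#' @param master_seed seed from which all per-run seeds are derived.
#' @return a `StabilityConfig` list.
#' @export
stability_config <- function(L = 100, nmi_threshold = 0.80,
                             min_fragment_frac = 0.05,
                             max_community_size = 100,
                             min_community_size = 4,
                             master_seed = 1L) {
  stopifnot(L >= 1, nmi_threshold > 0, nmi_threshold <= 1,
            min_fragment_frac >= 0, min_fragment_frac < 1,
            max_community_size > min_community_size)
  structure(list(L = L, nmi_threshold = nmi_threshold,
                 min_fragment_frac = min_fragment_frac,
                 max_community_size = max_community_size,
                 min_community_size = min_community_size,
                 master_seed = as.integer(master_seed)),
            class = "StabilityConfig")
}

#' Canonicalize a partition
#'
#' Renumbers community labels 1..K by first appearance in gene order, so
#' two partitions are equal up to label permutation iff their canonical
#' forms are identical.
#'
#' @param p named integer/character vector gene -> community label.
#' @return named integer vector with canonical labels.
#' @export
canonical_partition <- function(p) {
  labs <- as.character(p)
  stats::setNames(as.integer(factor(labs, levels = unique(labs))), names(p))
}

#' Signed modularity of a partition
#'
#' The layer-weighted signed modularity
#' `Q = (2m+ Q+ - 2m- Q-) / (2m+ + 2m-)`, where `Q+` (`Q-`) is the
#' gamma-resolution Newman-Girvan modularity of the positive-weight
#' (absolute-negative-weight) layer with its own null model. This is the
#' standard signed extension (Gomez, Jensen & Arenas): it rewards positive
#' weight inside communities and negative weight between them, and reduces
#' to plain modularity when the network has no negative edges.
#'
#' @param net a `CoexpressionNetwork`.
#' @param p named partition covering exactly `net$gene_ids`.
#' @param gamma resolution parameter.
#' @return a single numeric quality value.
#' @export
signed_quality <- function(net, p, gamma = 1) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  if (!setequal(names(p), net$gene_ids)) {
    stop("partition does not cover the network's genes")
  }
  memb <- as.integer(factor(as.character(p[net$gene_ids])))
  W <- net$weights
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  total <- sum(Wp) + sum(Wn)
  if (total <= 0) return(0)
  layer_term <- function(Wl) {
    m2 <- sum(Wl)
    if (m2 <= 0) return(0)
    k <- rowSums(Wl)
    within <- 0
    Ksq <- 0
    for (c in unique(memb)) {
      idx <- which(memb == c)
      within <- within + sum(Wl[idx, idx])
      Ksq <- Ksq + sum(k[idx])^2
    }
    within - gamma * Ksq / m2
  }
  (layer_term(Wp) - layer_term(Wn)) / total
}

#' One seeded Leiden run on a signed network
#'
#' Runs the move/refine/aggregate cycle optimizing [signed_quality()] at
#' resolution `gamma`, starting from a random assignment, with refinement
#' randomness `beta`. Deterministic given `seed`.
#'
#' @param net a `CoexpressionNetwork`.
#' @param cfg a [leiden_config()] (fields `gamma`, `beta`, `n_iterations`
#'   are used).
#' @param seed integer seed.
#' @return canonical partition (named integer vector).
#' @export
leiden_run <- function(net, cfg = leiden_config(), seed = 1L) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  if (length(net$gene_ids) == 0) stop("empty network")
  memb <- leiden_signed_cpp(net$weights, cfg$gamma, cfg$beta,
                            cfg$n_iterations, as.integer(seed))
  canonical_partition(stats::setNames(memb, net$gene_ids))
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(a;b) / (H(a) + H(b))` with natural-log entropies of the joint
#' label distribution. Equals 1 iff the partitions are identical up to
#' relabeling; when both partitions are trivial (one block each, so
#' `H(a) + H(b) = 0`) the convention is 1.
#'
#' @param p_a,p_b named partitions over the same gene set.
#' @return numeric in \[0, 1\].
#' @export
nmi <- function(p_a, p_b) {
  if (!setequal(names(p_a), names(p_b))) {
    stop("partitions cover different gene sets")
  }
  p_b <- p_b[names(p_a)]
  tab <- table(as.character(p_a), as.character(p_b))
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  max(0, min(1, 2 * mi / (ha + hb)))
}

#' Mean pairwise NMI of a partition ensemble
#'
#' The average NMI over all `L(L-1)/2` distinct unordered pairs. Identical
#' (canonically equal) partitions are grouped first so only unique pairs
#' are evaluated; the result equals the naive double loop exactly.
#'
#' @param ensemble list of >= 2 partitions over one gene set.
#' @return numeric in \[0, 1\].
#' @export
mean_pairwise_nmi <- function(ensemble) {
  L <- length(ensemble)
  if (L < 2) stop("need at least 2 partitions")
  canon <- vapply(ensemble, function(p) paste(canonical_partition(p),
                                              collapse = ","), character(1))
  counts <- table(canon)
  uniq <- ensemble[match(names(counts), canon)]
  cnt <- as.numeric(counts)
  total <- sum(cnt * (cnt - 1) / 2)  # identical pairs: NMI = 1
  U <- length(uniq)
  if (U > 1) {
    for (i in seq_len(U - 1)) {
      for (j in (i + 1):U) {
        total <- total + cnt[i] * cnt[j] * nmi(uniq[[i]], uniq[[j]])
      }
    }
  }
  total / (L * (L - 1) / 2)
}

#' Majority partition of an ensemble
#'
#' Partitions are grouped by canonical form (so relabelings count as the
#' same partition); the most frequent class wins. Frequency ties are broken
#' by higher [signed_quality()] (when `net` is supplied), then by the
#' lexicographically smallest canonical form, so the result is fully
#' deterministic.
#'
#' @param ensemble non-empty list of partitions.
#' @param net optional `CoexpressionNetwork` for the quality tie-break.
#' @param gamma resolution used in the tie-break.
#' @return list with `partition` (canonical) and `count`.
#' @export
majority_partition <- function(ensemble, net = NULL, gamma = 1) {
  stopifnot(length(ensemble) >= 1)
  canon_list <- lapply(ensemble, canonical_partition)
  keys <- vapply(canon_list, paste, character(1), collapse = ",")
  counts <- table(keys)
  best_n <- max(counts)
  tied_keys <- names(counts)[counts == best_n]
  cands <- canon_list[match(tied_keys, keys)]
  if (length(cands) > 1 && !is.null(net)) {
    q <- vapply(cands, function(p) signed_quality(net, p, gamma), numeric(1))
    keep <- abs(q - max(q)) < 1e-12
    cands <- cands[keep]
    tied_keys <- tied_keys[keep]
  }
  pick <- order(tied_keys)[1]
  list(partition = cands[[pick]], count = as.integer(best_n))
}

#' Apply the stability acceptance rules to a majority partition
#'
#' A partition is accepted iff it is simultaneously stable
#' (`mean_nmi >= nmi_threshold`), non-trivial (at least two communities)
#' and not fragmented (no community smaller than
#' `min_fragment_frac * net_size`; the comparison is strict, so a
#' community of exactly the threshold size is allowed).
#'
#' @param sr a `StabilityResult` (from [run_stability()]) with `mean_nmi`
#'   and `majority` filled.
#' @param net_size number of genes of the (sub)network the ensemble was run
#'   on.
#' @param cfg a [stability_config()].
#' @return `sr` with `accepted` and `rejection_reasons` filled.
#' @export
assess_partition <- function(sr, net_size, cfg) {
  reasons <- character(0)
  if (sr$mean_nmi < cfg$nmi_threshold) reasons <- c(reasons, "unstable")
  sizes <- table(sr$majority)
  if (length(sizes) < 2) reasons <- c(reasons, "trivial")
  if (any(sizes < cfg$min_fragment_frac * net_size)) {
    reasons <- c(reasons, "fragmented")
  }
  sr$accepted <- length(reasons) == 0
  sr$rejection_reasons <- reasons
  sr
}

#' Run a seeded Leiden ensemble for one (gamma, beta) configuration
#'
#' Performs `L` runs with seeds derived deterministically from
#' `cfg$master_seed`, gamma, beta and the run index; computes the majority
#' partition and the mean pairwise NMI, and applies [assess_partition()].
#'
#' @param net a `CoexpressionNetwork`.
#' @param gamma,beta Leiden parameters for this configuration.
#' @param lcfg a [leiden_config()] (for `n_iterations`).
#' @param scfg a [stability_config()].
#' @return a `StabilityResult` list: `gamma`, `beta`, `L`, `ensemble`,
#'   `mean_nmi`, `majority`, `majority_count`, `accepted`,
#'   `rejection_reasons`.
#' @export
run_stability <- function(net, gamma, beta, lcfg, scfg) {
  cfg <- lcfg
  cfg$gamma <- gamma
  cfg$beta <- beta
  seeds <- vapply(seq_len(scfg$L),
                  function(j) derive_seed(scfg$master_seed, gamma, beta, j),
                  integer(1))
  ensemble <- lapply(seeds, function(s) leiden_run(net, cfg, seed = s))
  maj <- majority_partition(ensemble, net = net, gamma = gamma)
  sr <- structure(
    list(gamma = gamma, beta = beta, L = scfg$L, ensemble = ensemble,
         mean_nmi = if (scfg$L >= 2) mean_pairwise_nmi(ensemble) else 1,
         majority = maj$partition, majority_count = maj$count,
         accepted = NA, rejection_reasons = character(0)),
    class = "StabilityResult"
  )
  assess_partition(sr, length(net$gene_ids), scfg)
}

#' Scan the (gamma, beta) grid and select the most stable configuration
#'
#' For every grid configuration, runs a seeded ensemble, takes the majority
#' partition and assesses it; among accepted configurations the one with
#' the highest mean NMI wins (ties: smaller gamma, then smaller beta).
#'
#' @param net a `CoexpressionNetwork`.
#' @param lcfg a [leiden_config()] providing `gamma_grid` and `beta_grid`.
#' @param scfg a [stability_config()].
#' @return the winning `StabilityResult`, or `NULL` if no configuration is
#'   accepted. The attribute `"scan"` holds a data frame summarizing every
#'   configuration tried.
#' @export
select_config <- function(net, lcfg = leiden_config(),
                          scfg = stability_config()) {
  results <- list()
  scan <- list()
  for (gamma in lcfg$gamma_grid) {
    for (beta in lcfg$beta_grid) {
      sr <- run_stability(net, gamma, beta, lcfg, scfg)
      results[[length(results) + 1]] <- sr
      scan[[length(scan) + 1]] <- data.frame(
        gamma = gamma, beta = beta, mean_nmi = sr$mean_nmi,
        n_communities = length(unique(sr$majority)),
        majority_count = sr$majority_count, accepted = sr$accepted,
        reasons = paste(sr$rejection_reasons, collapse = ";"))
    }
  }
  scan <- do.call(rbind, scan)
  accepted <- Filter(function(sr) isTRUE(sr$accepted), results)
  if (!length(accepted)) return(NULL)  # scan retrievable via run_stability
  key <- vapply(accepted, function(sr)
    c(-sr$mean_nmi, sr$gamma, sr$beta), numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ])
  out <- accepted[[ord[1]]]
  attr(out, "scan") <- scan
  out
}

#' Hierarchical stability-driven community detection
#'
#' Depth-first recursion over the co-expression network: at each node,
#' [select_config()] picks the most stable accepted partition of the node's
#' subnetwork; each resulting community is discarded (size <
#' `min_community_size`), kept as a leaf (size < `max_community_size`) or
#' recursed into (size >= `max_community_size`). A node of at least
#' `max_community_size` genes where no configuration is accepted is marked
#' unresolvable and retained (never silently dropped). Every root gene ends
#' up in exactly one of leaves / discarded / unresolved.
#'
#' @param net root `CoexpressionNetwork` (>= `min_community_size` genes).
#' @param lcfg a [leiden_config()].
#' @param scfg a [stability_config()].
#' @param verbose print progress per node.
#' @return a `CommunityTree`: list with `root_genes`, `leaves` (list of
#'   gene-id vectors, the final communities), `discarded`, `unresolved`,
#'   `paths` (gene -> community index per depth), `nodes` (per-node
#'   stability reports) and `max_depth`.
#' @export
hierarchical_detect <- function(net, lcfg = leiden_config(),
                                scfg = stability_config(), verbose = FALSE) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  if (length(net$gene_ids) < scfg$min_community_size) {
    stop("root network smaller than min_community_size")
  }
  env <- new.env()
  env$leaves <- list()
  env$discarded <- list()
  env$unresolved <- list()
  env$nodes <- list()
  env$paths <- stats::setNames(vector("list", length(net$gene_ids)),
                               net$gene_ids)
  env$max_depth <- 0L

  recurse <- function(genes, depth, path) {
    sub <- subnetwork(net, genes)
    sr <- select_config(sub, lcfg, scfg)
    env$nodes[[length(env$nodes) + 1]] <- list(
      depth = depth, size = length(genes),
      gamma = if (!is.null(sr)) sr$gamma else NA_real_,
      beta = if (!is.null(sr)) sr$beta else NA_real_,
      mean_nmi = if (!is.null(sr)) sr$mean_nmi else NA_real_,
      majority_count = if (!is.null(sr)) sr$majority_count else NA_integer_,
      accepted = !is.null(sr),
      scan = attr(sr, "scan"))
    if (verbose) {
      message(sprintf("depth %d node (%d genes): %s", depth, length(genes),
                      if (is.null(sr)) "unresolvable"
                      else sprintf("gamma=%g beta=%g <NMI>=%.3f",
                                   sr$gamma, sr$beta, sr$mean_nmi)))
    }
    if (is.null(sr)) {
      env$unresolved[[length(env$unresolved) + 1]] <- genes
      return(invisible())
    }
    env$max_depth <- max(env$max_depth, depth)
    comms <- split(names(sr$majority), sr$majority)
    for (k in seq_along(comms)) {
      cg <- comms[[k]]
      for (g in cg) env$paths[[g]] <- c(path, k)
      if (length(cg) < scfg$min_community_size) {
        env$discarded[[length(env$discarded) + 1]] <- cg
      } else if (length(cg) < scfg$max_community_size) {
        env$leaves[[length(env$leaves) + 1]] <- cg
      } else {
        recurse(cg, depth + 1L, c(path, k))
      }
    }
    invisible()
  }
  recurse(net$gene_ids, 1L, integer(0))

  structure(
    list(root_genes = net$gene_ids, leaves = env$leaves,
         discarded = env$discarded, unresolved = env$unresolved,
         paths = env$paths, nodes = env$nodes, max_depth = env$max_depth),
    class = "CommunityTree"
  )
}

#' Final communities of a tree
#' @param tree a `CommunityTree`.
#' @return named list `community_1`, `community_2`, ... of gene-id vectors.
#' @export
community_leaves <- function(tree) {
  stopifnot(inherits(tree, "CommunityTree"))
  stats::setNames(tree$leaves,
                  if (length(tree$leaves))
                    paste0("community_", seq_along(tree$leaves))
                  else character(0))
}

#' @export
print.CommunityTree <- function(x, ...) {
  cat(sprintf(paste0("CommunityTree: %d genes -> %d leaf communities, ",
                     "%d discarded set(s), %d unresolved node(s), depth %d\n"),
              length(x$root_genes), length(x$leaves), length(x$discarded),
              length(x$unresolved), x$max_depth))
  invisible(x)
}

#' Compare a leaf partition with a reference partition
#'
#' Builds the flat partition induced by the tree's leaves (plus one block
#' per discarded/unresolved set) restricted to genes present in `reference`
#' and returns the NMI against it. Used to score recovery of planted
#' modules.
#'
#' @param tree a `CommunityTree`.
#' @param reference named vector gene -> reference module id; genes absent
#'   from the reference (e.g. noise genes coded 0, if `exclude_zero`) can be
#'   excluded.
#' @param exclude_zero drop reference entries equal to 0 before comparing.
#' @return NMI in \[0, 1\].
#' @export
leaf_partition_nmi <- function(tree, reference, exclude_zero = TRUE) {
  stopifnot(inherits(tree, "CommunityTree"))
  if (exclude_zero) reference <- reference[reference != 0]
  flat <- integer(0)
  groups <- c(tree$leaves, tree$discarded, tree$unresolved)
  for (k in seq_along(groups)) {
    flat[groups[[k]]] <- k
  }
  common <- intersect(names(reference), names(flat))
  if (!length(common)) stop("no genes shared with the reference partition")
  nmi(stats::setNames(flat[common], common),
      stats::setNames(as.integer(factor(reference[common])), common))
}
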