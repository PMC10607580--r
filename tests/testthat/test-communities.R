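test_that("signed modularity reproduces hand-evaluated toys", {
  # two disjoint 4-cliques of unit weight: true partition scores 0.5
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  ids <- paste0("x", 1:8)
  dimnames(W) <- list(ids, ids)
  net <- coexcomm:::new_network(W, ids, "pearson")
  truep <- setNames(rep(1:2, each = 4), ids)
  expect_equal(signed_quality(net, truep, gamma = 1), 0.5)
  # trivial single community on an all-positive network scores 0
  expect_equal(signed_quality(net, setNames(rep(1, 8), ids), gamma = 1), 0)
  # flipping every edge sign negates Q under the same partition
  netf <- coexcomm:::new_network(-W, ids, "pearson")
  expect_equal(signed_quality(netf, truep, 1), -signed_quality(net, truep, 1))
  p2 <- setNames(c(1, 1, 2, 2, 1, 2, 1, 2), ids)
  expect_equal(signed_quality(netf, p2, 1.3), -signed_quality(net, p2, 1.3))
  expect_error(signed_quality(net, truep[1:5], 1), "cover")
})

test_that("a leiden run recovers the exhaustively-verified signed optimum", {
  net <- block_network(c(5, 5), w_in = 0.9, w_out = -0.3)
  ids <- net$gene_ids
  planted <- setNames(rep(1:2, each = 5), ids)
  # enumerate every partition into at most 2 blocks; planted must maximize Q
  best_q <- -Inf
  for (mask in 0:(2^9 - 1)) {
    p <- setNames(c(1L, as.integer(intToBits(mask))[1:9] + 1L), ids)
    q <- signed_quality(net, p, gamma = 1)
    if (q > best_q) best_q <- q
  }
  expect_equal(signed_quality(net, planted, 1), best_q)
  found <- leiden_run(net, leiden_config(), seed = 7)
  expect_equal(nmi(found, planted), 1)
})

test_that("leiden runs are deterministic and a clique stays whole", {
  net <- block_network(12, w_in = 0.8, w_out = 0)
  p <- leiden_run(net, leiden_config(), seed = 1)
  expect_length(unique(p), 1)
  big <- block_network(c(15, 10), w_in = 0.9, w_out = -0.2)
  expect_identical(leiden_run(big, leiden_config(), seed = 42),
                   leiden_run(big, leiden_config(), seed = 42))
})

test_that("nmi matches brute-force entropy arithmetic", {
  genes <- paste0("g", 1:6)
  p_a <- setNames(c(1, 1, 1, 2, 2, 2), genes)
  p_b <- setNames(c(1, 1, 2, 2, 3, 3), genes)
  # frozen from the joint-entropy oracle; igraph::compare(method="nmi") agrees
  expect_equal(nmi(p_a, p_b), 0.5158037, tolerance = 1e-6)
  expect_equal(nmi(p_a, p_b), nmi_oracle(p_a, p_b), tolerance = 1e-12)

  # label-permuted copy is identical
  expect_equal(nmi(p_a, setNames(c(9, 9, 9, 4, 4, 4), genes)), 1)
  # singletons vs one block: I = 0 while H(a) > 0
  expect_equal(nmi(setNames(1:6, genes), setNames(rep(1, 6), genes)), 0)
  # both trivial: convention 1
  expect_equal(nmi(setNames(rep(1, 6), genes), setNames(rep(2, 6), genes)), 1)
  expect_error(nmi(p_a, p_b[1:5]), "different gene sets")

  genes50 <- paste0("g", 1:50)
  for (s in 1:20) {
    a <- random_partition(genes50, sample(2:6, 1), seed = s)
    b <- random_partition(genes50, sample(2:6, 1), seed = 1000 + s)
    expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-10)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  }
})

test_that("mean pairwise nmi equals the naive double loop", {
  genes <- paste0("g", 1:30)
  ens <- lapply(1:20, function(s) random_partition(genes, 4, seed = 200 + s))
  naive <- 0
  for (i in 1:19) for (j in (i + 1):20) naive <- naive + nmi(ens[[i]], ens[[j]])
  naive <- naive / choose(20, 2)
  expect_equal(mean_pairwise_nmi(ens), naive, tolerance = 1e-12)

  same <- lapply(1:5, function(i) setNames(c(1, 1, 2, 2), paste0("g", 1:4)))
  expect_equal(mean_pairwise_nmi(same), 1)
  expect_error(mean_pairwise_nmi(same[1]), "at least 2")
})

test_that("majority voting groups relabelings and breaks ties deterministically", {
  genes <- paste0("g", 1:6)
  P <- setNames(c(1, 1, 1, 2, 2, 2), genes)
  Q <- setNames(c(1, 2, 1, 2, 1, 2), genes)
  res <- majority_partition(list(P, P, Q))
  expect_equal(res$partition, canonical_partition(P))
  expect_equal(res$count, 2L)

  relabeled <- setNames(c(7, 7, 7, 3, 3, 3), genes)
  res2 <- majority_partition(list(P, relabeled, Q))
  expect_equal(res2$count, 2L)
  expect_equal(res2$partition, canonical_partition(P))

  # all distinct: the lexicographically smallest canonical form wins
  R <- setNames(c(1, 2, 2, 1, 1, 2), genes)
  res3 <- majority_partition(list(Q, R, P))
  expect_equal(res3$count, 1L)
  keys <- vapply(lapply(list(Q, R, P), canonical_partition),
                 paste, character(1), collapse = ",")
  expect_equal(paste(res3$partition, collapse = ","), sort(keys)[1])
})

test_that("acceptance rules: stability, triviality and fragmentation bounds", {
  genes <- paste0("g", 1:100)
  cfg <- stability_config(L = 10, master_seed = 1)
  make_sr <- function(majority, mean_nmi) {
    structure(list(gamma = 1, beta = 0.05, L = 10, ensemble = list(),
                   mean_nmi = mean_nmi, majority = majority,
                   majority_count = 5L, accepted = NA,
                   rejection_reasons = character(0)),
              class = "StabilityResult")
  }
  # a 4-gene community in a 100-gene network is below 5% -> fragmented
  maj4 <- setNames(c(rep(1, 48), rep(2, 48), rep(3, 4)), genes)
  sr <- assess_partition(make_sr(maj4, 0.9), 100, cfg)
  expect_false(sr$accepted)
  expect_equal(sr$rejection_reasons, "fragmented")
  # a 5-gene community is not less than 5%: accepted (strict inequality)
  maj5 <- setNames(c(rep(1, 50), rep(2, 45), rep(3, 5)), genes)
  sr <- assess_partition(make_sr(maj5, 0.9), 100, cfg)
  expect_true(sr$accepted)
  # mean NMI just under the threshold -> unstable
  sr <- assess_partition(make_sr(maj5, 0.79), 100, cfg)
  expect_false(sr$accepted)
  expect_equal(sr$rejection_reasons, "unstable")
  # single community -> trivial
  sr <- assess_partition(make_sr(setNames(rep(1, 100), genes), 0.95), 100, cfg)
  expect_false(sr$accepted)
  expect_equal(sr$rejection_reasons, "trivial")
})

test_that("raising the stability threshold only shrinks the accepted set", {
  net <- block_network(c(8, 8, 8), w_in = 0.7, w_out = -0.1)
  lcfg <- leiden_config(gamma_grid = c(0.75, 1), beta_grid = c(0.05, 0.1))
  accepted_at <- function(thr) {
    scfg <- stability_config(L = 8, nmi_threshold = thr, master_seed = 3)
    acc <- character(0)
    for (g in lcfg$gamma_grid) {
      for (b in lcfg$beta_grid) {
        sr <- run_stability(net, g, b, lcfg, scfg)
        if (sr$accepted) acc <- c(acc, paste(g, b))
      }
    }
    acc
  }
  lo <- accepted_at(0.5)
  hi <- accepted_at(0.95)
  expect_lte(length(hi), length(lo))
  expect_true(all(hi %in% lo))
})

test_that("grid selection returns the most stable accepted configuration", {
  net <- block_network(c(10, 10), w_in = 0.9, w_out = -0.3)
  res <- select_config(net, leiden_config(gamma_grid = 1, beta_grid = 0.05),
                       stability_config(L = 10, master_seed = 5))
  expect_false(is.null(res))
  expect_equal(res$mean_nmi, 1)
  expect_equal(res$majority_count, 10L)
  expect_length(unique(res$majority), 2)

  # pure-noise correlations: no configuration should be accepted
  set.seed(6)
  v <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:40)))
  noise_net <- build_network(expression_matrix(v))
  res2 <- select_config(noise_net,
                        leiden_config(gamma_grid = 1, beta_grid = 0.05),
                        stability_config(L = 10, master_seed = 6))
  expect_null(res2)
})

test_that("hierarchical detection recurses, discards and conserves genes", {
  # flat case: two clear blocks under 100 genes -> depth-1 leaves only
  net <- block_network(c(40, 40), w_in = 0.8, w_out = -0.2)
  tree <- hierarchical_detect(net,
                              leiden_config(gamma_grid = 1, beta_grid = 0.05),
                              stability_config(L = 10, master_seed = 2))
  expect_length(tree$leaves, 2)
  expect_equal(tree$max_depth, 1L)
  expect_setequal(unlist(tree$leaves), net$gene_ids)

  # 3-gene satellite is discarded but conserved
  net2 <- block_network(c(30, 20, 3), w_in = 0.9, w_out = -0.4)
  tree2 <- hierarchical_detect(net2, leiden_config(),
                               stability_config(L = 10, master_seed = 2))
  expect_length(tree2$discarded, 1)
  expect_length(tree2$discarded[[1]], 3)
  expect_setequal(c(unlist(tree2$leaves), unlist(tree2$discarded),
                    unlist(tree2$unresolved)), net2$gene_ids)
  # leaves are pairwise disjoint
  expect_equal(anyDuplicated(unlist(tree2$leaves)), 0)

  expect_error(hierarchical_detect(block_network(3),
                                   leiden_config(),
                                   stability_config(L = 2, master_seed = 1)),
               "smaller than min_community_size")
})

test_that("nested planted hierarchies are recovered level by level", {
  d <- synthetic_design(n_samples_per_class = c(tumor = 100, normal = 100),
                        module_sizes = c(150, 150),
                        nesting = list("1" = c(60, 50, 40),
                                       "2" = c(60, 50, 40)),
                        rho_within = 0.8, rho_super = 0.3,
                        n_noise_genes = 0, discriminative_flags = FALSE,
                        seed = 13)
  ds <- generate_nested_dataset(d)
  net <- build_network(ds$matrix)
  tree <- hierarchical_detect(net, leiden_config(),
                              stability_config(L = 20, master_seed = 4))
  first <- vapply(tree$paths, function(p) p[1], numeric(1))
  expect_length(unique(first), 2)
  expect_length(tree$leaves, 6)
  expect_true(all(lengths(tree$leaves) < 100))
  expect_gte(leaf_partition_nmi(tree, ds$truth$gene_submodule), 0.9)
})
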