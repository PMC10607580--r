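#' Assemble a pipeline configuration
#'
#' Collects every stage's settings plus input/output paths. All stage seeds
#' are derived deterministically from `master_seed`, so a full run is
#' reproducible bit-for-bit.
#'
#' @param out_dir output directory (created if absent).
#' @param input_matrix,input_labels paths to the expression matrix (TSV,
#'   genes in rows) and labels (TSV); ignored when `simulate` is given.
#' @param external_matrix,external_labels optional paths of the independent
#'   validation cohort.
#' @param simulate optional [synthetic_design()]: generate the input
#'   instead of reading it.
#' @param master_seed integer master seed.
#' @param log2_input apply [log2_transform()] (with `log2_offset`) first.
#' @param log2_offset pseudo-count for the log2 transform.
#' @param quantile apply [quantile_normalize()].
#' @param unsupervised_check run WSS/silhouette/k-means diagnostics and the
#'   class-merging contingency check.
#' @param k_max largest k for the cluster diagnostics.
#' @param merge_classes classes pooled in the contingency agreement check.
#' @param network_method correlation measure for [build_network()].
#' @param leiden,stability,boruta,split,rf,cv stage configurations (see the
#'   respective `*_config()` constructors).
#' @param accuracy_cutoff retention threshold (percent) for
#'   [rank_communities()].
#' @param positive_class label treated as the positive (tumor) class; all
#'   other labels are pooled as the negative class.
#' @param shap list of SHAP settings: `n_communities` (how many
#'   top-ranked communities to explain), `n_permutations`,
#'   `background_size`, `n_explain`, `top_k`.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir,
                            input_matrix = NULL, input_labels = NULL,
                            external_matrix = NULL, external_labels = NULL,
                            simulate = NULL,
                            master_seed = 1L,
                            log2_input = FALSE, log2_offset = 0,
                            quantile = TRUE,
                            unsupervised_check = TRUE, k_max = 6,
                            merge_classes = c("normal", "peritumoral"),
                            network_method = "pearson",
                            leiden = leiden_config(),
                            stability = stability_config(),
                            boruta = boruta_config(),
                            split = split_config(),
                            rf = rf_config(),
                            cv = cv_config(),
                            accuracy_cutoff = 90,
                            positive_class = "tumor",
                            shap = list()) {
  if (is.null(simulate) && is.null(input_matrix)) {
    stop("either `input_matrix` or `simulate` must be given")
  }
  for (p in c(input_matrix, input_labels, external_matrix, external_labels)) {
    if (!is.null(p) && normalizePath(dirname(p), mustWork = FALSE) ==
        normalizePath(out_dir, mustWork = FALSE)) {
      stop("output directory must be distinct from input paths")
    }
  }
  shap <- modifyList(list(n_communities = 2, n_permutations = 100,
                          background_size = 50, n_explain = 30, top_k = 20),
                     shap)
  structure(
    list(out_dir = out_dir, input_matrix = input_matrix,
         input_labels = input_labels, external_matrix = external_matrix,
         external_labels = external_labels, simulate = simulate,
         master_seed = as.integer(master_seed),
         log2_input = log2_input, log2_offset = log2_offset,
         quantile = quantile, unsupervised_check = unsupervised_check,
         k_max = k_max, merge_classes = merge_classes,
         network_method = network_method,
         leiden = leiden, stability = stability, boruta = boruta,
         split = split, rf = rf, cv = cv,
         accuracy_cutoff = accuracy_cutoff,
         positive_class = positive_class, shap = shap),
    class = "PipelineConfig"
  )
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  state$log <- c(state$log, line)
  message(line)
  invisible(state)
}

binary_labels <- function(labels, positive) {
  out <- ifelse(labels == positive, positive, "non_tumor")
  stats::setNames(out, names(labels))
}

#' Run the full discovery pipeline
#'
#' Executes preprocess -> network -> hierarchical community detection ->
#' per-community feature selection and repeated-CV classification ->
#' community ranking -> optional external validation -> Shapley
#' explanation of the top communities, writing every stage artifact plus a
#' manifest into `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @return the run manifest (list), invisibly; artifacts on disk:
#'   `normalized_expression.tsv`, `cluster_diagnostics.json`,
#'   `partition.tsv`, `stability_report.json`, `community_report.tsv`,
#'   `external_validation.tsv` (when an external cohort is given),
#'   `shap_<community>.json`, `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  state <- new.env()
  state$log <- character(0)
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  timings <- list()
  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t, "secs")), 3)
    res
  }

  # --- input ------------------------------------------------------------
  m <- stage("input", {
    if (!is.null(cfg$simulate)) {
      pipeline_log(state, "simulating input dataset")
      ds <- if (!is.null(cfg$simulate$nesting)) {
        generate_nested_dataset(cfg$simulate)
      } else {
        generate_dataset(cfg$simulate)
      }
      write_synthetic_dataset(ds, file.path(cfg$out_dir, "simulated"))
      state$truth <- ds$truth
      ds$matrix
    } else {
      pipeline_log(state, "reading %s", cfg$input_matrix)
      labels <- if (!is.null(cfg$input_labels)) read_labels(cfg$input_labels)
      read_expression_matrix(cfg$input_matrix, labels = labels)
    }
  })
  if (is.null(m$labels)) stop("pipeline stage 'input' failed: no sample labels")

  # --- preprocess -------------------------------------------------------
  m <- stage("preprocess", {
    if (cfg$log2_input) m <- log2_transform(m, cfg$log2_offset)
    if (cfg$quantile) m <- quantile_normalize(m)
    write_expression_matrix(m, out("normalized_expression.tsv"))
    m
  })

  if (cfg$unsupervised_check) {
    stage("unsupervised_check", {
      seed <- derive_seed(cfg$master_seed, "kmeans")
      diag <- cluster_diagnostics(m, k_max = cfg$k_max, seed = seed)
      cl <- kmeans_cluster(m, k = 2, seed = seed)
      res <- list(k_values = diag$k_values, wss = diag$wss,
                  silhouette = diag$silhouette, chosen_k = diag$chosen_k)
      merge <- intersect(cfg$merge_classes, unique(m$labels))
      if (length(merge)) {
        ca <- contingency_agreement(m$labels, cl, merge)
        res$contingency <- as.data.frame(ca$table)
        res$merge_classes <- merge
        res$agreement_pct <- ca$agreement_pct
        pipeline_log(state, "merge check: %.2f%% of %s co-assigned",
                     ca$agreement_pct, paste(merge, collapse = "+"))
      }
      jsonlite::write_json(res, out("cluster_diagnostics.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  # --- network + communities -------------------------------------------
  net <- stage("network", build_network(m, method = cfg$network_method))
  scfg <- cfg$stability
  scfg$master_seed <- derive_seed(cfg$master_seed, "communities")
  tree <- stage("communities", {
    pipeline_log(state, "hierarchical detection on %d genes",
                 length(net$gene_ids))
    tree <- hierarchical_detect(net, cfg$leiden, scfg)
    write_partition(tree, out("partition.tsv"))
    jsonlite::write_json(
      lapply(tree$nodes, function(n) n[c("depth", "size", "gamma", "beta",
                                         "mean_nmi", "majority_count",
                                         "accepted")]),
      out("stability_report.json"), auto_unbox = TRUE, digits = NA)
    pipeline_log(state, "%d leaf communities, %d discarded, %d unresolved",
                 length(tree$leaves), length(tree$discarded),
                 length(tree$unresolved))
    tree
  })

  # --- per-community selection + classification ------------------------
  labels_bin <- binary_labels(m$labels, cfg$positive_class)
  split_cfg <- cfg$split
  split_cfg$seed <- derive_seed(cfg$master_seed, "split")
  sets <- split_selection_classification(m$sample_ids, labels_bin, split_cfg)
  leaves <- community_leaves(tree)
  reports <- list()
  selected_genes <- list()
  report_rows <- list()
  stage("classify", {
    for (cm in names(leaves)) {
      genes <- leaves[[cm]]
      X_sel <- t(m$values[genes, sets$selection, drop = FALSE])
      bcfg <- cfg$boruta
      bcfg$seed <- derive_seed(cfg$master_seed, "boruta", cm)
      br <- boruta_select(X_sel, labels_bin[sets$selection], bcfg)
      sel <- br$selected
      if (!length(sel)) {
        pipeline_log(state, "%s: no features confirmed; skipped", cm)
        report_rows[[cm]] <- data.frame(
          community = cm, cardinality = length(genes), n_selected = 0,
          accuracy_mean = NA, accuracy_sd = NA, auc_mean = NA, auc_sd = NA,
          f1_mean = NA, f1_sd = NA, logloss_mean = NA, logloss_sd = NA)
        next
      }
      selected_genes[[cm]] <- sel
      X_cls <- t(m$values[sel, sets$classification, drop = FALSE])
      rf_cfg <- cfg$rf
      rf_cfg$seed <- derive_seed(cfg$master_seed, "rf", cm)
      cv_cfg <- cfg$cv
      cv_cfg$seed <- derive_seed(cfg$master_seed, "cv", cm)
      rep <- repeated_cv(X_cls, labels_bin[sets$classification],
                         rf_cfg, cv_cfg, positive = cfg$positive_class)
      reports[[cm]] <- rep
      s <- rep$summary
      get <- function(metric, col) s[[col]][s$metric == metric]
      report_rows[[cm]] <- data.frame(
        community = cm, cardinality = length(genes), n_selected = length(sel),
        accuracy_mean = get("accuracy", "mean"), accuracy_sd = get("accuracy", "sd"),
        auc_mean = get("auc", "mean"), auc_sd = get("auc", "sd"),
        f1_mean = get("f1", "mean"), f1_sd = get("f1", "sd"),
        logloss_mean = get("logloss", "mean"), logloss_sd = get("logloss", "sd"))
      pipeline_log(state, "%s: %d/%d genes selected, CV accuracy %.2f%%",
                   cm, length(sel), length(genes), get("accuracy", "mean"))
    }
    report <- do.call(rbind, report_rows)
    rownames(report) <- NULL
    write.table(report, out("community_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  ranked <- rank_communities(reports, cfg$accuracy_cutoff)
  pipeline_log(state, "%d of %d communities exceed %.0f%% accuracy",
               length(ranked), length(leaves), cfg$accuracy_cutoff)

  # --- external validation ---------------------------------------------
  models <- list()
  for (cm in names(selected_genes)) {
    rf_cfg <- cfg$rf
    rf_cfg$seed <- derive_seed(cfg$master_seed, "final_rf", cm)
    models[[cm]] <- train_rf(
      t(m$values[selected_genes[[cm]], sets$classification, drop = FALSE]),
      labels_bin[sets$classification], rf_cfg, positive = cfg$positive_class)
  }
  external <- NULL
  if (!is.null(cfg$external_matrix)) {
    external <- stage("external_validation", {
      ext_labels <- binary_labels(read_labels(cfg$external_labels),
                                  cfg$positive_class)
      ext <- read_expression_matrix(cfg$external_matrix, labels = ext_labels)
      rows <- lapply(ranked, function(cm) {
        ms <- external_validate(models[[cm]], ext)
        data.frame(community = cm,
                   cardinality = length(leaves[[cm]]),
                   accuracy = ms$accuracy, auc = ms$auc, f1 = ms$f1,
                   logloss = ms$logloss)
      })
      tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(community = character(0), cardinality = integer(0),
                   accuracy = numeric(0), auc = numeric(0), f1 = numeric(0),
                   logloss = numeric(0))
      write.table(tab, out("external_validation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tab
    })
  }

  # --- SHAP explanation of the top communities --------------------------
  explained <- stage("xai", {
    targets <- head(ranked, cfg$shap$n_communities)
    res <- list()
    for (cm in targets) {
      sel <- selected_genes[[cm]]
      X_bg <- t(m$values[sel, sets$classification, drop = FALSE])
      bg_idx <- with_seed(derive_seed(cfg$master_seed, "shap_bg", cm), {
        sample.int(nrow(X_bg), min(cfg$shap$background_size, nrow(X_bg)))
      })
      # explain held-out samples: the selection split never trained this model
      X_ex <- t(m$values[sel, sets$selection, drop = FALSE])
      ex_idx <- with_seed(derive_seed(cfg$master_seed, "shap_ex", cm), {
        sample.int(nrow(X_ex), min(cfg$shap$n_explain, nrow(X_ex)))
      })
      exp <- approx_shap(models[[cm]], X_ex[ex_idx, , drop = FALSE],
                         X_bg[bg_idx, , drop = FALSE],
                         n_permutations = cfg$shap$n_permutations,
                         seed = derive_seed(cfg$master_seed, "shap", cm))
      summ <- shap_summary(exp, cfg$shap$top_k)
      jsonlite::write_json(
        list(community = cm, base_value = exp$base_value,
             ranking = summ$ranking, top = summ$top,
             local_accuracy = shap_local_accuracy(exp)),
        out(paste0("shap_", cm, ".json")), auto_unbox = TRUE, digits = NA)
      res[[cm]] <- summ
    }
    res
  })

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("coexcomm")),
    r_version = R.version.string,
    master_seed = cfg$master_seed,
    config = cfg[setdiff(names(cfg), "simulate")],
    simulated = !is.null(cfg$simulate),
    n_genes = length(net$gene_ids),
    n_samples = length(m$sample_ids),
    n_leaves = length(tree$leaves),
    ranked_communities = ranked,
    explained_communities = names(explained),
    timings_sec = timings,
    input_checksums = {
      paths <- c(cfg$input_matrix, cfg$input_labels, cfg$external_matrix,
                 cfg$external_labels)
      if (length(paths)) as.list(tools::md5sum(paths)) else list()
    }
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  writeLines(state$log, out("run.log"))
  pipeline_log(state, "pipeline finished in %.1f s",
               as.numeric(difftime(Sys.time(), t0, "secs")))
  invisible(manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' blocks `leiden`, `stability`, `boruta`, `split`, `rf`, `cv`, `shap` and
#' `simulate` override fields of the corresponding constructors.
#'
#' @param path YAML file.
#' @param overrides optional named list applied on top of the file (e.g.
#'   from command-line flags).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  build <- function(ctor, key) {
    args <- raw[[key]] %||% list()
    do.call(ctor, args)
  }
  sim <- NULL
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    if (!is.null(args$n_samples_per_class)) {
      args$n_samples_per_class <- unlist(args$n_samples_per_class)
    }
    if (!is.null(args$discriminative_flags)) {
      args$discriminative_flags <- unlist(args$discriminative_flags)
    }
    sim <- do.call(synthetic_design, args)
  }
  keep <- intersect(names(raw),
                    c("out_dir", "input_matrix", "input_labels",
                      "external_matrix", "external_labels", "master_seed",
                      "log2_input", "log2_offset", "quantile",
                      "unsupervised_check", "k_max", "merge_classes",
                      "network_method", "accuracy_cutoff", "positive_class",
                      "shap"))
  args <- raw[keep]
  args$simulate <- sim
  args$leiden <- build(leiden_config, "leiden")
  args$stability <- build(stability_config, "stability")
  args$boruta <- build(boruta_config, "boruta")
  args$split <- build(split_config, "split")
  args$rf <- build(rf_config, "rf")
  args$cv <- build(cv_config, "cv")
  do.call(pipeline_config, args)
}
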