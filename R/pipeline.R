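#' Pipeline configuration
#'
#' Collects the input paths, tunable parameters and stage toggles for
#' [run_pipeline()]. A YAML file with the same keys can be loaded with
#' [read_pipeline_config()]; explicit arguments override file values.
#'
#' @param expression Path to the expression TSV (genes or probes in rows).
#' @param candidates Path to the candidate gene list (one symbol per line).
#' @param gmt Path to the pathway GMT file.
#' @param clinical Optional path to the clinical TSV.
#' @param annotation Optional probe annotation TSV (`probe_id`,
#'   `gene_symbol`); when given, probes are collapsed to genes first.
#' @param validation_expression Optional expression TSV of an independent
#'   cohort for cross-cohort validation.
#' @param output_dir Directory for all artifacts.
#' @param metric Distance metric for clustering.
#' @param k Number of subtypes (default 3).
#' @param alpha Allocation significance threshold (default 0.05).
#' @param enrichment_alpha Adjusted-p threshold for enrichment (default 0.05).
#' @param C SVM soft-margin penalty (default 1).
#' @param folds Cross-validation folds (default 5).
#' @param n_permutations Permutation draws for validation significance.
#' @param seed Integer seed driving every stochastic stage.
#' @param do_clinical,do_classification,do_validation Stage toggles;
#'   validation additionally requires `validation_expression`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, candidates, gmt, clinical = NULL,
                            annotation = NULL, validation_expression = NULL,
                            output_dir = "copdsubtype_out",
                            metric = c("correlation", "euclidean"), k = 3L,
                            alpha = 0.05, enrichment_alpha = 0.05, C = 1,
                            folds = 5L, n_permutations = 1000L, seed = 1L,
                            do_clinical = !is.null(clinical),
                            do_classification = TRUE,
                            do_validation = !is.null(validation_expression)) {
  metric <- match.arg(metric)
  cfg <- list(expression = expression, candidates = candidates, gmt = gmt,
              clinical = clinical, annotation = annotation,
              validation_expression = validation_expression,
              output_dir = output_dir, metric = metric, k = as.integer(k),
              alpha = alpha, enrichment_alpha = enrichment_alpha, C = C,
              folds = as.integer(folds),
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), do_clinical = do_clinical,
              do_classification = do_classification,
              do_validation = do_validation)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$k < 2L) stop("k must be >= 2")
  if (cfg$folds < 2L) stop("folds must be >= 2")
  required <- c("expression", "candidates", "gmt")
  for (key in required) {
    if (is.null(cfg[[key]])) stop("config is missing the '", key, "' path")
    if (!file.exists(cfg[[key]])) {
      stop("input path for '", key, "' does not exist: ", cfg[[key]])
    }
  }
  for (key in c("clinical", "annotation", "validation_expression")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("input path for '", key, "' does not exist: ", cfg[[key]])
    }
  }
  if (cfg$do_clinical && is.null(cfg$clinical)) {
    stop("do_clinical = TRUE but no clinical path given")
  }
  if (cfg$do_validation && is.null(cfg$validation_expression)) {
    stop("do_validation = TRUE but no validation_expression path given")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full subtyping analysis
#'
#' Executes preprocess, subtype discovery, gene allocation, pathway
#' enrichment + deviation scoring, optional clinical association, SVM
#' training with cross-validation, and optional cross-cohort validation.
#' Every artifact is written under the output directory as TSV/JSON; a run
#' manifest with per-file checksums makes reruns verifiable. Reruns with the
#' same config and seed produce byte-identical result tables.
#'
#' @param config A `pipeline_config`.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("copdsubtype")),
                   config = unclass(config), stages = list(), files = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }

  # -- preprocess ------------------------------------------------------------
  norm <- stage("preprocess", {
    expr <- read_expression_table(config$expression)
    if (!is.null(config$annotation)) {
      ann <- utils::read.table(config$annotation, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      expr <- collapse_probes(expr, ann)
    }
    zscore_rows(expr)
  })
  zmat <- norm$matrix
  utils::write.table(norm$report, file.path(out, "normalization_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  candidates <- read_gene_list(config$candidates)
  cand_mat <- stage("subset_candidates", subset_to_candidates(zmat, candidates))

  # -- subtype discovery -----------------------------------------------------
  assignment <- stage("subtype_discovery",
                      discover_subtypes(cand_mat, k = config$k,
                                        metric = config$metric))
  write_subtypes(assignment, file.path(out, "subtypes.tsv"))
  export_dendrogram_newick(assignment$tree, file.path(out, "dendrogram.nwk"))
  utils::write.table(
    data.frame(metric = config$metric, k = config$k,
               cophenetic = assignment$cophenetic),
    file.path(out, "clustering_qc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # -- gene allocation -------------------------------------------------------
  allocation <- stage("gene_allocation", {
    tab <- differential_t_test(cand_mat, assignment)
    allocate_genes(tab, alpha = config$alpha)
  })
  write_allocation_table(allocation, file.path(out, "allocation.tsv"))
  writeLines(allocation$common, file.path(out, "common_genes.txt"))

  # -- pathway enrichment + deviation ---------------------------------------
  pathways <- read_gmt(config$gmt)
  pw <- stage("pathway_analysis", {
    universe <- intersect(rownames(zmat),
                          unique(unlist(pathways, use.names = FALSE)))
    records <- lapply(allocation$sets, function(gset) {
      fisher_enrichment(intersect(gset, universe), pathways, universe,
                        alpha = config$enrichment_alpha)
    })
    parts <- partition_pathways(records)
    scored_ids <- if (length(parts$common)) parts$common else
      sort(unique(unlist(lapply(records, function(d) d$pathway[d$enriched]))))
    if (!length(scored_ids)) {
      message("no enriched pathways; scoring all pathways")
      scored_ids <- names(pathways)
    }
    dev <- deviation_score_table(cand_mat, assignment,
                                 pathways[scored_ids], allocation$sets)
    list(records = records, parts = parts, dev = dev,
         scored = pathways[scored_ids])
  })
  for (s in names(pw$records)) {
    utils::write.table(pw$records[[s]],
                       file.path(out, paste0("enrichment_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(pw$parts$common, file.path(out, "common_pathways.txt"))
  utils::write.table(pw$dev, file.path(out, "deviation_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- clinical --------------------------------------------------------------
  if (config$do_clinical) {
    clin_tab <- stage("clinical_association", {
      clinical <- read_clinical_table(config$clinical)
      clinical <- clinical[clinical$sample_id %in% names(assignment$labels), ,
                           drop = FALSE]
      clinical_association_table(clinical, assignment)
    })
    utils::write.table(clin_tab, file.path(out, "clinical_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- classification --------------------------------------------------------
  model <- NULL
  features <- NULL
  if (config$do_classification) {
    cls <- stage("classification", {
      # primary sets keep per-subtype features distinct; fall back to the
      # full allocated set for a subtype with no primary genes
      ss <- allocation$primary_sets
      empty <- lengths(ss) == 0L
      ss[empty] <- allocation$sets[empty]
      schema <- deviation_feature_schema(pw$scored, ss, pw$dev)
      ref <- rowMeans(cand_mat)
      feats <- sample_deviation_features(cand_mat, schema, ref)
      fit <- train_classifier(feats, assignment, C = config$C)
      cv <- cross_validate_roc(feats, assignment, folds = config$folds,
                               seed = config$seed, C = config$C)
      list(features = feats, model = fit, cv = cv)
    })
    model <- cls$model
    features <- cls$features
    save_svm_model(model, file.path(out, "svm_model.json"))
    cv_tab <- do.call(rbind, lapply(cls$cv$per_class, function(pc) {
      data.frame(subtype = pc$class, auc = pc$auc, accuracy = pc$accuracy)
    }))
    cv_tab$overall_accuracy <- cls$cv$overall_accuracy
    utils::write.table(cv_tab, file.path(out, "cv_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (pc in cls$cv$per_class) {
      utils::write.table(pc$roc,
                         file.path(out, sprintf("roc_subtype%s.tsv", pc$class)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # -- cross-cohort validation ----------------------------------------------
  if (config$do_validation) {
    if (is.null(model)) stop("validation requires the classification stage")
    val <- stage("cross_cohort_validation", {
      vexpr <- read_expression_table(config$validation_expression)
      harm <- harmonize_features(cand_mat, vexpr)
      vassign <- discover_subtypes(harm$validation, k = config$k,
                                   metric = config$metric)
      vfeats <- sample_deviation_features(
        harm$validation, model$schema$pathway_genes,
        model$schema$reference_means)
      pred <- predict_labels(model, vfeats)
      cm <- build_confusion_matrix(vassign$labels, pred)
      perm <- permutation_significance(
        relabel_clusters(vassign$labels, cm$mapping), pred,
        n_permutations = config$n_permutations, seed = config$seed)
      list(assignment = vassign, cm = cm, perm = perm)
    })
    write_subtypes(val$assignment, file.path(out, "validation_subtypes.tsv"))
    write_confusion_matrix(val$cm, file.path(out, "validation_confusion.tsv"))
    perm_df <- as.data.frame(val$perm)
    perm_df$n_permutations <- attr(val$perm, "n_permutations")
    utils::write.table(perm_df, file.path(out, "validation_permutation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  produced <- setdiff(list.files(out, full.names = TRUE), file.path(out, "manifest.json"))
  manifest$files <- lapply(stats::setNames(produced, basename(produced)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Apply a cluster->model relabeling recorded in a confusion_matrix mapping
# (names = cluster class, values = matched model class).
relabel_clusters <- function(labels, mapping) {
  if (is.null(mapping)) return(labels)
  out <- mapping[as.character(labels)]
  names(out) <- names(labels)
  out
}
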