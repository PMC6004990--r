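ref_counts <- function() {
  path <- system.file("extdata", "validation_confusion_counts.tsv",
                      package = "copdsubtype")
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

test_that("harmonization restricts to shared genes and re-normalizes", {
  set.seed(41)
  disc <- matrix(rnorm(50), 10, 5,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("d", 1:5)))
  val <- matrix(rnorm(48, mean = 7, sd = 3), 8, 6,
                dimnames = list(sprintf("g%02d", 3:10), paste0("v", 1:6)))
  harm <- harmonize_features(disc, val)
  expect_identical(rownames(harm$discovery), rownames(harm$validation))
  expect_setequal(rownames(harm$discovery), sprintf("g%02d", 3:10))
  expect_lt(max(abs(rowMeans(harm$validation))), 1e-9)
  expect_lt(max(abs(apply(harm$validation, 1, sd) - 1)), 1e-9)

  disjoint <- matrix(rnorm(20), 4, 5,
                     dimnames = list(paste0("x", 1:4), paste0("v", 1:5)))
  expect_error(harmonize_features(disc, disjoint), "shared")
})

test_that("confusion matrices count, total and ratio correctly", {
  # perfect agreement: 10 samples, 2 balanced classes
  cl <- setNames(rep(1:2, each = 5), paste0("s", 1:10))
  cm <- suppressMessages(build_confusion_matrix(cl, cl))
  expect_equal(unname(diag(cm$counts)), c(5, 5))
  expect_equal(unname(cm$ratios), c(100, 100))
  expect_equal(cm$grand_total, 10)

  pred <- cl
  pred["s1"] <- 2L
  cm2 <- suppressMessages(build_confusion_matrix(cl, pred, match = FALSE))
  expect_equal(unname(cm2$counts[, "1"]), c(4, 1))
  expect_equal(unname(cm2$ratios), c(80, 100))

  bad <- setNames(rep(1L, 9), paste0("s", 1:9))
  expect_error(build_confusion_matrix(cl, bad), "sample sets differ")
})

test_that("label matching undoes an arbitrary cluster renumbering", {
  set.seed(43)
  pred <- setNames(sample(1:3, 90, replace = TRUE), paste0("s", 1:90))
  remap <- c(3L, 1L, 2L)
  clustered <- setNames(remap[pred], names(pred))  # same partition, renamed
  cm <- suppressMessages(build_confusion_matrix(clustered, pred))
  expect_equal(sum(diag(cm$counts)), 90)
  expect_equal(unname(cm$ratios), c(100, 100, 100))
  # the recorded mapping inverts the renumbering
  expect_identical(unname(cm$mapping[as.character(remap)]), 1:3)
})

test_that("published-style count tables reproduce totals and ratios", {
  cm <- as_confusion_matrix(ref_counts())
  expect_equal(unname(cm$column_totals), c(205, 219, 88, 105))
  expect_equal(cm$grand_total, 617)
  expect_equal(unname(cm$ratios), c(68.8, 71.7, 63.6, 68.6))
  expect_equal(unname(cm$ratios[2]), round(100 * 157 / 219, 1))
  expect_equal(unname(cm$ratios[3]), round(100 * 56 / 88, 1))

  # ratios are invariant to a simultaneous identical relabeling
  perm <- c(2, 4, 1, 3)
  cm_perm <- as_confusion_matrix(ref_counts()[perm, perm])
  expect_equal(sort(unname(cm_perm$ratios)), sort(unname(cm$ratios)))
})

test_that("permutation p-values respect the Monte-Carlo lower bound", {
  cl <- setNames(rep(1:3, each = 20), paste0("s", 1:60))
  res <- permutation_significance(cl, cl, n_permutations = 999L, seed = 5)
  expect_true(all(res$p >= 1 / 1000))
  # perfect agreement on 3 balanced classes: bound attained
  expect_equal(res$p, rep(1 / 1000, 3))
  expect_error(permutation_significance(cl, cl, n_permutations = 0L),
               ">= 1")
})

test_that("permutation p-values are reproducible and super-uniform under the null", {
  set.seed(51)
  n_rep <- 120
  ps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cl <- setNames(sample(1:3, 60, replace = TRUE), paste0("s", 1:60))
    pred <- setNames(sample(1:3, 60, replace = TRUE), paste0("s", 1:60))
    res <- permutation_significance(cl, pred, n_permutations = 200L,
                                    seed = r)
    res2 <- permutation_significance(cl, pred, n_permutations = 200L,
                                     seed = r)
    expect_identical(res$p, res2$p)
    ps[r] <- res$p[1]
  }
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
  }
  # and p is not degenerate at small values: median near the middle
  expect_gt(stats::median(ps), 0.2)
  expect_lt(stats::median(ps), 0.85)
})

# mirror of the pipeline's internal relabeling helper, kept here so the test
# exercises the exported mapping contract
relabel_clusters_for_test <- function(labels, mapping) {
  out <- mapping[as.character(labels)]
  names(out) <- names(labels)
  out
}

test_that("cross-cohort predictions agree with the validation clustering on a high-separation fixture", {
  skip_if_not_installed("mclust")
  cfg <- small_cohort_config()
  coh <- generate_cohort(cfg)
  z <- zscore_rows(coh$expression)$matrix
  cand <- subset_to_candidates(z, coh$truth$candidate_genes)
  asg <- discover_subtypes(cand, k = 3)
  alloc <- allocate_genes(differential_t_test(cand, asg))
  pw <- generate_pathway_annotation(cfg, rownames(z),
                                    coh$truth$informative_genes)
  universe <- intersect(rownames(z), unique(unlist(pw, use.names = FALSE)))
  records <- lapply(alloc$sets, function(s) {
    fisher_enrichment(intersect(s, universe), pw, universe)
  })
  common <- partition_pathways(records)$common
  dev <- deviation_score_table(cand, asg, pw[common], alloc$sets)
  schema <- deviation_feature_schema(pw[common], alloc$primary_sets, dev)
  feats <- sample_deviation_features(cand, schema, rowMeans(cand))
  model <- train_classifier(feats, asg)
  cv <- cross_validate_roc(feats, asg, folds = 5, seed = 2)

  val <- generate_validation_cohort(cfg, coh$truth, n_controls = 0L,
                                    n_samples = 60L)
  harm <- harmonize_features(cand, val$expression)
  vfeats <- sample_deviation_features(harm$validation,
                                      model$schema$pathway_genes,
                                      model$schema$reference_means)
  pred <- predict_labels(model, vfeats)
  # predictions agree with the planted labels (up to label matching)
  ari <- mclust::adjustedRandIndex(pred, val$truth$true_labels)
  expect_gte(ari, 0.8)

  vassign <- discover_subtypes(harm$validation, k = 3)
  cm <- suppressMessages(build_confusion_matrix(vassign$labels, pred))
  agreement <- sum(diag(cm$counts)) / cm$grand_total
  # cross-cohort agreement comparable to within-cohort CV accuracy
  cv_acc <- mean(vapply(cv$per_class, `[[`, 0, "accuracy"))
  expect_gte(agreement, cv_acc - 0.10)

  perm <- permutation_significance(
    relabel_clusters_for_test(vassign$labels, cm$mapping), pred,
    n_permutations = 500L, seed = 9)
  expect_true(all(perm$p < 0.05))
})
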