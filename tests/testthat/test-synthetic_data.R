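test_that("config invariants are enforced", {
  expect_error(synth_config(subtype_proportions = c(0.5, 0.4), k_subtypes = 3),
               "length")
  expect_error(synth_config(subtype_proportions = c(0.6, 0.6, 0.1) / 1.0,
                            k_subtypes = 3), "sum to 1")
  expect_error(synth_config(frac_informative = 1.2), "frac_informative")
  expect_error(synth_config(pathway_size_range = c(1, 10)), ">= 2")
  expect_error(synth_config(n_genes = 50, n_candidate_genes = 20,
                            pathway_size_range = c(10, 100)),
               "exceed n_genes")
})

test_that("same config and seed give bit-identical cohorts", {
  cfg <- small_cohort_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$true_labels, b$truth$true_labels)
  # pathway draws do not perturb the expression stream
  p1 <- generate_pathway_annotation(cfg, rownames(a$expression),
                                    a$truth$informative_genes)
  c2 <- generate_cohort(cfg)
  expect_identical(a$expression, c2$expression)
  p2 <- generate_pathway_annotation(cfg, rownames(a$expression),
                                    a$truth$informative_genes)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("cohort structure matches the configuration", {
  cfg <- small_cohort_config(n_samples = 61L,
                             subtype_proportions = c(0.5, 0.3, 0.2))
  coh <- generate_cohort(cfg)
  expect_identical(dim(coh$expression), c(400L, 61L))
  expect_identical(sort(unique(coh$truth$true_labels)), 1:3)
  expect_length(coh$truth$true_labels, 61L)
  expect_true(all(coh$truth$informative_genes %in%
                    coh$truth$candidate_genes))
  expect_equal(nrow(coh$clinical), 61L)
  expect_true(all(coh$clinical$sex %in% c("male", "female")))
})

test_that("planted subtypes are recovered at high separation", {
  skip_if_not_installed("mclust")
  cfg <- small_cohort_config(effect_size = 5, frac_informative = 1)
  coh <- generate_cohort(cfg)
  z <- zscore_rows(coh$expression)$matrix
  cand <- subset_to_candidates(z, coh$truth$candidate_genes)
  asg <- discover_subtypes(cand, k = 3)
  ari <- mclust::adjustedRandIndex(asg$labels, coh$truth$true_labels)
  expect_gte(ari, 0.9)
})

test_that("pathway generator honours sizes and planted enrichment", {
  cfg <- small_cohort_config(n_pathways = 20L, pathway_size_range = c(2L, 2L))
  coh <- generate_cohort(cfg)
  pw <- generate_pathway_annotation(cfg, rownames(coh$expression),
                                    coh$truth$informative_genes)
  expect_true(all(lengths(pw) == 2L))
  expect_true(all(unlist(pw) %in% rownames(coh$expression)))

  cfg_big <- small_cohort_config(pathway_size_range = c(10L, 40L))
  expect_error(generate_pathway_annotation(cfg_big, paste0("g", 1:9)),
               "universe")

  # planted pathways are informative-gene heavy, background ones are not
  pw2 <- generate_pathway_annotation(cfg_big, rownames(coh$expression),
                                     coh$truth$informative_genes,
                                     frac_enriched = 0.5)
  frac_inf <- vapply(pw2, function(s) {
    mean(s %in% coh$truth$informative_genes)
  }, 0)
  n_enr <- round(0.5 * length(pw2))
  expect_gt(mean(frac_inf[seq_len(n_enr)]),
            mean(frac_inf[-seq_len(n_enr)]) + 0.2)
})

test_that("validation cohorts reuse the discovery mean model", {
  cfg <- small_cohort_config()
  coh <- generate_cohort(cfg)
  val <- generate_validation_cohort(cfg, coh$truth, n_controls = 10L,
                                    n_samples = 30L)
  expect_identical(dim(val$expression), c(400L, 40L))
  expect_identical(sum(val$truth$true_labels == 0L), 10L)
  expect_error(generate_validation_cohort(cfg, coh$truth, n_controls = -1),
               ">= 0")

  # full gene universe => harmonize_features restricts to the identity set
  z_d <- zscore_rows(coh$expression)$matrix
  harm <- harmonize_features(z_d, val$expression)
  expect_setequal(rownames(harm$discovery), rownames(z_d))
  expect_identical(rownames(harm$discovery), rownames(harm$validation))

  # subsetted universe emulates a platform difference
  val_sub <- generate_validation_cohort(cfg, coh$truth, n_controls = 0L,
                                        n_samples = 30L,
                                        gene_subset_frac = 0.3)
  expect_equal(nrow(val_sub$expression), round(0.3 * 400))
})

test_that("controls form their own cluster at k+1 cuts when separation is high", {
  cfg <- small_cohort_config(effect_size = 6)
  coh <- generate_cohort(cfg)
  val <- generate_validation_cohort(cfg, coh$truth, n_controls = 15L,
                                    n_samples = 45L)
  z <- zscore_rows(val$expression)$matrix
  cand <- subset_to_candidates(z, coh$truth$candidate_genes)
  # euclidean geometry: a noise-only class sits together near the baseline;
  # under correlation distance mutually-uncorrelated controls never do
  asg <- discover_subtypes(cand, k = 4, metric = "euclidean")
  ctrl <- names(val$truth$true_labels)[val$truth$true_labels == 0L]
  ctrl_cluster <- asg$labels[ctrl]
  # all controls in one cluster, and that cluster is essentially controls
  expect_length(unique(ctrl_cluster), 1L)
  members <- names(asg$labels)[asg$labels == unique(ctrl_cluster)]
  expect_gte(mean(members %in% ctrl), 0.9)
})

test_that("cohort files round-trip through the standard formats", {
  cfg <- small_cohort_config(n_genes = 60L, n_candidate_genes = 20L,
                             n_samples = 12L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expr <- read_expression_table(paths[["expression"]])
  expect_lt(max(abs(expr - coh$expression)), 1e-12)
  clin <- read_clinical_table(paths[["clinical"]])
  expect_identical(clin$sample_id, coh$clinical$sample_id)
  expect_identical(read_gene_list(paths[["candidates"]]),
                   coh$truth$candidate_genes)
})
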