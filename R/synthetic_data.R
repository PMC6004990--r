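#' Configuration for a synthetic COPD-like cohort
#'
#' Defines a cohort with `k_subtypes` planted molecular subtypes expressed
#' through a subset of candidate genes. Informative candidate genes carry a
#' mean shift of `effect_size * noise_sd` in one randomly chosen subtype;
#' all other genes share a common mean. Clinical lung-function covariates
#' (FEV1, FEV1/FVC as percent scales) differ across subtypes by
#' `clinical_shift`, sex proportions differ by subtype, and age is shared.
#'
#' Defaults mirror the shape of a blood-expression COPD discovery cohort:
#' 229 samples in three subtypes of 98/53/78 and a 213-gene candidate list.
#'
#' @param n_genes Total number of genes.
#' @param n_candidate_genes Number of candidate (disease-associated) genes;
#'   the candidate list is the first `n_candidate_genes` gene symbols.
#' @param n_samples Number of samples.
#' @param k_subtypes Number of planted subtypes (>= 2).
#' @param subtype_proportions Simplex vector of length `k_subtypes`.
#' @param effect_size Mean shift per informative gene, in SD units.
#' @param frac_informative Fraction of candidate genes carrying subtype effects.
#' @param noise_sd Gaussian noise SD per gene.
#' @param n_pathways Number of synthetic pathways.
#' @param pathway_size_range Integer pair (min, max) pathway size.
#' @param clinical_shift Subtype separation of FEV1 / FEV1-FVC means
#'   (percent-scale units).
#' @param seed Integer seed; one root generator drives deterministic
#'   stage-specific substreams.
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(n_genes = 2000L, n_candidate_genes = 213L,
                         n_samples = 229L, k_subtypes = 3L,
                         subtype_proportions = c(98, 53, 78) / 229,
                         effect_size = 3, frac_informative = 0.75,
                         noise_sd = 1, n_pathways = 50L,
                         pathway_size_range = c(10L, 60L),
                         clinical_shift = 6, seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1, k_subtypes >= 2,
            n_candidate_genes >= 1, n_candidate_genes <= n_genes,
            effect_size >= 0, noise_sd > 0, n_pathways >= 1,
            length(pathway_size_range) == 2)
  if (frac_informative < 0 || frac_informative > 1) {
    stop("frac_informative must lie in [0, 1]")
  }
  if (length(subtype_proportions) != k_subtypes) {
    stop("subtype_proportions must have length k_subtypes")
  }
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("subtype_proportions must sum to 1 (within 1e-9)")
  }
  if (any(subtype_proportions <= 0)) stop("subtype_proportions must be positive")
  if (pathway_size_range[1L] < 2) stop("minimum pathway size must be >= 2")
  if (pathway_size_range[2L] > n_genes) {
    stop("maximum pathway size cannot exceed n_genes")
  }
  if (pathway_size_range[1L] > pathway_size_range[2L]) {
    stop("pathway_size_range must be (min, max) with min <= max")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_candidate_genes = as.integer(n_candidate_genes),
    n_samples = as.integer(n_samples),
    k_subtypes = as.integer(k_subtypes),
    subtype_proportions = subtype_proportions,
    effect_size = effect_size,
    frac_informative = frac_informative,
    noise_sd = noise_sd,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    clinical_shift = clinical_shift,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Deterministic per-stage substreams from the root seed, so e.g. drawing
# pathways never perturbs the expression draws.
substream_seeds <- function(config) {
  set.seed(config$seed)
  s <- sample.int(2147483646L, 4L)
  names(s) <- c("expression", "clinical", "pathways", "validation")
  s
}

subtype_counts <- function(proportions, n) {
  counts <- diff(c(0L, round(cumsum(proportions) * n)))
  if (any(counts < 1)) stop("a subtype received no samples; increase n_samples")
  counts
}

#' Generate a synthetic discovery cohort
#'
#' @param config A [synth_config()].
#' @return List with `expression` (gene x sample matrix), `clinical`
#'   (data.frame) and `truth` (a `cohort_truth`: planted labels, informative
#'   genes, per-gene subtype mean matrix, candidate list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ss <- substream_seeds(config)
  k <- config$k_subtypes
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  candidates <- genes[seq_len(config$n_candidate_genes)]

  set.seed(ss[["expression"]])
  n_inf <- round(config$frac_informative * config$n_candidate_genes)
  informative <- if (n_inf > 0) sort(sample(candidates, n_inf)) else character()
  counts <- subtype_counts(config$subtype_proportions, config$n_samples)
  labels <- rep(seq_len(k), counts)
  mu <- matrix(0, config$n_genes, k,
               dimnames = list(genes, paste0("subtype", seq_len(k))))
  if (n_inf > 0) {
    target <- sample(k, n_inf, replace = TRUE)
    mu[cbind(match(informative, genes), target)] <-
      config$effect_size * config$noise_sd
  }
  X <- mu[, labels, drop = FALSE] +
    matrix(stats::rnorm(config$n_genes * config$n_samples, 0, config$noise_sd),
           config$n_genes, config$n_samples)
  colnames(X) <- sprintf("SAMP%04d", seq_len(config$n_samples))
  names(labels) <- colnames(X)

  set.seed(ss[["clinical"]])
  clinical <- simulate_clinical(labels, k, config$clinical_shift)

  truth <- structure(list(
    true_labels = labels,
    informative_genes = informative,
    subtype_means = mu,
    candidate_genes = candidates,
    noise_sd = config$noise_sd
  ), class = "cohort_truth")
  list(expression = X, clinical = clinical, truth = truth)
}

# Subtype 2 is the most impaired (lowest FEV1 / FEV1-FVC, most female),
# mirroring the severity gradient the pipeline is meant to detect.
simulate_clinical <- function(labels, k, clinical_shift) {
  sev <- rep(0.2, k)
  sev[1L] <- 0
  if (k >= 2) sev[2L] <- 1
  if (k >= 3) sev[3L] <- 0.4
  p_female <- rep(0.5, k)
  p_female[1L] <- 0.42
  if (k >= 2) p_female[2L] <- 0.64
  if (k >= 3) p_female[3L] <- 0.58
  n <- length(labels)
  fev1 <- pmax(5, stats::rnorm(n, 58 - clinical_shift * sev[labels], 12))
  ratio <- pmax(5, stats::rnorm(n, 55 - 0.8 * clinical_shift * sev[labels], 7))
  age <- pmax(30, stats::rnorm(n, 65, 8))
  sex <- ifelse(stats::runif(n) < p_female[labels], "female", "male")
  data.frame(sample_id = names(labels), FEV1 = fev1, FEV1_FVC = ratio,
             age = age, sex = sex, stringsAsFactors = FALSE)
}

#' Generate a synthetic pathway annotation
#'
#' Draws `n_pathways` gene sets from the universe. A configurable fraction of
#' pathways is planted to be enriched for the informative genes; the rest are
#' uniform draws.
#'
#' @param config A [synth_config()].
#' @param gene_universe Character vector of gene symbols.
#' @param informative_genes Character vector (may be empty).
#' @param frac_enriched Fraction of pathways with planted enrichment.
#' @param informative_weight Target fraction of an enriched pathway's members
#'   drawn from the informative genes.
#' @return A `gene_sets` collection.
#' @export
generate_pathway_annotation <- function(config, gene_universe,
                                        informative_genes = character(),
                                        frac_enriched = 0.5,
                                        informative_weight = 0.7) {
  stopifnot(inherits(config, "synth_config"))
  if (!length(gene_universe)) stop("gene_universe must be nonempty")
  rng <- config$pathway_size_range
  if (rng[2L] > length(gene_universe)) {
    stop("maximum pathway size exceeds the gene universe size")
  }
  ss <- substream_seeds(config)
  set.seed(ss[["pathways"]])
  n <- config$n_pathways
  sizes <- if (rng[1L] == rng[2L]) rep(rng[1L], n) else
    sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
  n_enr <- round(frac_enriched * n)
  inf <- intersect(informative_genes, gene_universe)
  noninf <- setdiff(gene_universe, inf)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    size <- sizes[i]
    if (i <= n_enr && length(inf)) {
      n_in <- min(length(inf), max(1L, round(informative_weight * size)))
      n_in <- max(n_in, size - length(noninf))
      members <- c(sample(inf, n_in),
                   if (size - n_in > 0) sample(noninf, size - n_in))
    } else {
      members <- sample(gene_universe, size)
    }
    sets[[i]] <- sort(members)
  }
  names(sets) <- sprintf("PW%04d", seq_len(n))
  desc <- ifelse(seq_len(n) <= n_enr, "planted enriched set", "background set")
  gene_sets(sets, desc)
}

#' Generate a synthetic validation cohort
#'
#' Draws new samples from the discovery cohort's per-gene subtype mean model,
#' plus an optional control class with its own mean vector (default: the
#' shared baseline). A subset of the discovery gene universe can be kept to
#' emulate a platform difference.
#'
#' @param config A [synth_config()].
#' @param discovery_truth `cohort_truth` from [generate_cohort()].
#' @param n_controls Number of control samples (>= 0); controls carry the
#'   label 0 in the returned truth.
#' @param n_samples Number of diseased samples (default `config$n_samples`).
#' @param gene_subset_frac Fraction of discovery genes retained.
#' @param control_mean Optional numeric mean vector for controls (length
#'   `n_genes`); defaults to the shared baseline (zero vector).
#' @return List with `expression`, `clinical` and `truth` as in
#'   [generate_cohort()].
#' @export
generate_validation_cohort <- function(config, discovery_truth,
                                       n_controls = 57L, n_samples = NULL,
                                       gene_subset_frac = 1,
                                       control_mean = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(discovery_truth, "cohort_truth"))
  if (n_controls < 0) stop("n_controls must be >= 0")
  if (is.null(discovery_truth$subtype_means)) {
    stop("discovery_truth must carry the per-gene subtype mean matrix")
  }
  mu <- discovery_truth$subtype_means
  genes <- rownames(mu)
  k <- ncol(mu)
  if (is.null(n_samples)) n_samples <- config$n_samples
  if (is.null(control_mean)) control_mean <- rep(0, length(genes))
  stopifnot(length(control_mean) == length(genes))

  ss <- substream_seeds(config)
  set.seed(ss[["validation"]])
  counts <- subtype_counts(config$subtype_proportions, n_samples)
  labels <- c(rep(seq_len(k), counts), rep(0L, n_controls))
  M <- cbind(mu, control = control_mean)
  colidx <- ifelse(labels == 0L, k + 1L, labels)
  n_total <- length(labels)
  X <- M[, colidx, drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n_total, 0, config$noise_sd),
           length(genes), n_total)
  colnames(X) <- sprintf("VAL%04d", seq_len(n_total))
  names(labels) <- colnames(X)

  copd <- labels[labels != 0L]
  clin_copd <- simulate_clinical(copd, k, config$clinical_shift)
  if (n_controls > 0) {
    ctrl_ids <- names(labels)[labels == 0L]
    clin_ctrl <- data.frame(
      sample_id = ctrl_ids,
      FEV1 = pmax(5, stats::rnorm(n_controls, 88, 10)),
      FEV1_FVC = pmax(5, stats::rnorm(n_controls, 79, 5)),
      age = pmax(30, stats::rnorm(n_controls, 62, 9)),
      sex = ifelse(stats::runif(n_controls) < 0.5, "female", "male"),
      stringsAsFactors = FALSE
    )
    clinical <- rbind(clin_copd, clin_ctrl)
  } else {
    clinical <- clin_copd
  }

  if (gene_subset_frac < 1) {
    keep <- sort(sample(genes, round(gene_subset_frac * length(genes))))
    X <- X[keep, , drop = FALSE]
  }
  truth <- structure(list(
    true_labels = labels,
    informative_genes = discovery_truth$informative_genes,
    subtype_means = mu,
    candidate_genes = discovery_truth$candidate_genes,
    noise_sd = config$noise_sd
  ), class = "cohort_truth")
  list(expression = X, clinical = clinical, truth = truth)
}

#' Write a synthetic cohort to the pipeline's standard file formats
#'
#' @param cohort List from [generate_cohort()] or
#'   [generate_validation_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    candidates = file.path(dir, paste0(prefix, "_candidates.txt"))
  )
  write_expression_table(cohort$expression, paths[["expression"]])
  write_clinical_table(cohort$clinical, paths[["clinical"]])
  utils::write.table(
    data.frame(sample_id = names(cohort$truth$true_labels),
               true_label = unname(cohort$truth$true_labels)),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$truth$candidate_genes, paths[["candidates"]])
  invisible(paths)
}
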