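#' Pairwise sample distances for clustering
#'
#' The default metric is correlation distance, `1 - Pearson r` between sample
#' columns (range \[0, 2\]); Euclidean distance is available as an
#' alternative.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param metric `"correlation"` or `"euclidean"`.
#' @return Symmetric distance matrix with sample dimnames and zero diagonal.
#' @export
compute_distance <- function(mat, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  if (metric == "correlation") {
    sds <- apply(mat, 2L, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) {
      stop("zero-variance sample column(s) under correlation metric: ",
           paste(colnames(mat)[sds == 0 | !is.finite(sds)], collapse = ", "))
    }
    D <- 1 - stats::cor(mat)
  } else {
    D <- as.matrix(stats::dist(t(mat), method = "euclidean"))
  }
  diag(D) <- 0
  D[abs(D) < .Machine$double.eps * 4] <- 0
  D
}

#' Average-linkage (UPGMA) dendrogram
#'
#' @param dist_mat Symmetric distance matrix (or `dist` object).
#' @return An `hclust` tree with inter-cluster distance equal to the
#'   unweighted mean of all cross-pair distances.
#' @export
average_linkage_tree <- function(dist_mat) {
  d <- if (inherits(dist_mat, "dist")) dist_mat else stats::as.dist(dist_mat)
  if (attr(d, "Size") < 2L) stop("need at least 2 samples to cluster")
  stats::hclust(d, method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' dendrogram-implied (cophenetic) distances; a clustering-fidelity
#' diagnostic. 1 means the tree reproduces the distances exactly
#' (ultrametric input).
#'
#' @param tree An `hclust` tree.
#' @param dist_mat The distance matrix the tree was built from.
#' @return Scalar in \[-1, 1\].
#' @export
cophenetic_coefficient <- function(tree, dist_mat) {
  d <- if (inherits(dist_mat, "dist")) dist_mat else stats::as.dist(dist_mat)
  if (attr(d, "Size") < 3L) {
    stop("cophenetic correlation needs at least 3 samples")
  }
  stats::cor(as.vector(d), as.vector(stats::cophenetic(tree)))
}

#' Cut a dendrogram into k subtypes
#'
#' Labels are renumbered 1..k in decreasing cluster size; ties are broken by
#' the lexicographically smallest member sample id, so numbering is
#' reproducible across runs.
#'
#' @param tree An `hclust` tree.
#' @param k Number of subtypes, `2 <= k <= n`.
#' @param cophenetic_coef Optional precomputed cophenetic coefficient stored
#'   alongside the assignment.
#' @return A `subtype_assignment`: list with `labels` (named integer vector),
#'   `k`, `tree` and `cophenetic`.
#' @export
cut_to_subtypes <- function(tree, k, cophenetic_coef = NA_real_) {
  n <- length(tree$labels)
  if (k < 2 || k > n) stop("k must lie in [2, n]; got ", k, " for n = ", n)
  raw <- stats::cutree(tree, k = k)
  labels <- renumber_by_size(raw)
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 cophenetic = cophenetic_coef),
            class = "subtype_assignment")
}

# Renumber cluster labels 1..k by decreasing size, ties by smallest member id.
renumber_by_size <- function(raw) {
  ids <- names(raw)
  clusters <- sort(unique(raw))
  size <- vapply(clusters, function(cl) sum(raw == cl), 0L)
  min_id <- vapply(clusters, function(cl) min(ids[raw == cl]), "")
  ord <- clusters[order(-size, min_id)]
  out <- match(raw, ord)
  names(out) <- ids
  out
}

#' Discover molecular subtypes in one call
#'
#' Convenience wrapper: distance, UPGMA tree, cophenetic QC, cut at `k`.
#'
#' @inheritParams compute_distance
#' @inheritParams cut_to_subtypes
#' @return A `subtype_assignment` with the cophenetic coefficient filled in.
#' @export
discover_subtypes <- function(mat, k = 3, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  D <- compute_distance(mat, metric)
  tree <- average_linkage_tree(D)
  cc <- if (ncol(mat) >= 3L) cophenetic_coefficient(tree, D) else NA_real_
  cut_to_subtypes(tree, k, cophenetic_coef = cc)
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("Subtype assignment: ", length(x$labels), " samples in ", x$k,
      " subtypes\n", sep = "")
  print(table(subtype = x$labels))
  if (!is.na(x$cophenetic)) {
    cat("Cophenetic correlation coefficient:", round(x$cophenetic, 3), "\n")
  }
  invisible(x)
}

#' Write a subtype assignment as TSV
#'
#' @param assignment A `subtype_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subtypes <- function(assignment, path) {
  utils::write.table(
    data.frame(sample_id = names(assignment$labels),
               subtype = unname(assignment$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths carry the merge heights.
#'
#' @param tree An `hclust` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
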