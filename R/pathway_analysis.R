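#' Over-representation test of a gene set against pathways
#'
#' One-sided Fisher's exact test (hypergeometric tail) of the overlap between
#' a query gene set and each pathway, within a fixed gene universe. P-values
#' are Benjamini-Hochberg adjusted across pathways within the query.
#'
#' @param query Character vector of gene symbols; must be a subset of
#'   `universe`.
#' @param pathways A `gene_sets` collection (members are intersected with the
#'   universe before testing).
#' @param universe Character vector of background gene symbols.
#' @param alpha Threshold on the adjusted p-value for the `enriched` flag.
#' @param adjust `"BH"` (default) or `"none"` for a raw-p sensitivity mode.
#' @return data.frame sorted by p: `pathway`, `overlap` (k), `query_size` (n),
#'   `pathway_size` (K), `universe_size` (M), `odds_ratio`, `p`, `p_adj`,
#'   `enriched`.
#' @export
fisher_enrichment <- function(query, pathways, universe, alpha = 0.05,
                              adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("empty query gene set")
  if (!length(universe)) stop("empty gene universe")
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  }
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(pathways), function(pid) {
    pset <- intersect(pathways[[pid]], universe)
    K <- length(pset)
    k <- length(intersect(query, pset))
    # P(X >= k) for X ~ Hypergeom(M, K, n)
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c0 <- K - k; d <- M - K - n + k
    or <- if (b == 0 || c0 == 0) Inf else (a * d) / (b * c0)
    data.frame(pathway = pid, overlap = k, query_size = n, pathway_size = K,
               universe_size = M, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$enriched <- out$p_adj < alpha
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition enriched pathways into common and subtype-unique
#'
#' @param per_subtype_records Named list (one element per subtype) of
#'   enrichment data.frames from [fisher_enrichment()].
#' @return List with `common` (pathway ids enriched in every subtype) and
#'   `unique` (per subtype: enriched there and in no other subtype).
#' @export
partition_pathways <- function(per_subtype_records) {
  if (length(per_subtype_records) < 2L) {
    stop("need enrichment records for at least 2 subtypes")
  }
  enr <- lapply(per_subtype_records,
                function(d) d$pathway[d$enriched])
  common <- sort(Reduce(intersect, enr))
  uniq <- lapply(seq_along(enr), function(i) {
    sort(setdiff(enr[[i]], unlist(enr[-i], use.names = FALSE)))
  })
  names(uniq) <- names(per_subtype_records)
  list(common = common, unique = uniq)
}

#' Pathway deviation score for one subtype
#'
#' For the N genes of pathway P that are also in the subtype's differential
#' gene set (and in the matrix), the score is the mean squared difference
#' between each gene's mean within the subtype and its mean over all samples:
#' `A(P) = (1/N) * sum_i (Xbar_i - Ybar_i)^2`. It is 0 iff the subtype means
#' equal the cohort means on every gene, and grows with how far the subtype's
#' pathway expression deviates from the cohort.
#'
#' @param mat Numeric matrix (genes x samples).
#' @param assignment A `subtype_assignment` (or named label vector).
#' @param pathway_genes Members of pathway P.
#' @param subtype_genes The subtype's differential gene set.
#' @param subtype The subtype label to score.
#' @return List with `A`, `N`, `genes`, `subtype_means` (Xbar) and
#'   `cohort_means` (Ybar), or `NULL` (with a message) when no usable genes
#'   remain.
#' @export
deviation_score <- function(mat, assignment, pathway_genes, subtype_genes,
                            subtype) {
  labels <- assignment_labels(assignment, colnames(mat))
  genes <- intersect(intersect(pathway_genes, subtype_genes), rownames(mat))
  if (!length(genes)) {
    message("no differential genes of subtype ", subtype,
            " in this pathway; skipped")
    return(NULL)
  }
  in_s <- labels == subtype
  if (!any(in_s)) stop("subtype ", subtype, " has no samples")
  xbar <- rowMeans(mat[genes, in_s, drop = FALSE])
  ybar <- rowMeans(mat[genes, , drop = FALSE])
  list(A = mean((xbar - ybar)^2), N = length(genes), genes = genes,
       subtype_means = xbar, cohort_means = ybar)
}

#' Deviation scores for many pathways across all subtypes
#'
#' @param mat Numeric matrix (genes x samples).
#' @param assignment A `subtype_assignment`.
#' @param pathways A `gene_sets` collection (typically the common enriched
#'   pathways).
#' @param subtype_sets Named list, per subtype, of differential gene sets
#'   (e.g. `allocate_genes(...)$sets`).
#' @return data.frame `pathway`, `subtype`, `N`, `A`; pathway/subtype pairs
#'   with no usable genes are skipped with a message.
#' @export
deviation_score_table <- function(mat, assignment, pathways, subtype_sets) {
  labels <- assignment_labels(assignment, colnames(mat))
  subtypes <- sort(unique(labels))
  rows <- list()
  for (pid in names(pathways)) {
    for (si in seq_along(subtypes)) {
      s <- subtypes[si]
      sset <- subtype_sets[[si]]
      res <- suppressMessages(
        deviation_score(mat, labels, pathways[[pid]], sset, s))
      if (is.null(res)) {
        message("pathway ", pid, " skipped for subtype ", s,
                ": no differential genes")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pid, subtype = s, N = res$N, A = res$A,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no pathway/subtype pair had usable genes")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot per-subtype pathway deviation profiles
#'
#' One line per subtype across pathways, mirroring the usual
#' deviation-profile display.
#'
#' @param dev_table data.frame from [deviation_score_table()].
#' @return A ggplot object.
#' @export
plot_deviation_profiles <- function(dev_table) {
  dev_table$subtype <- factor(dev_table$subtype)
  ggplot2::ggplot(dev_table,
                  ggplot2::aes(x = .data$pathway, y = .data$A,
                               group = .data$subtype,
                               colour = .data$subtype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "pathway", y = "deviation score A(P)",
                  colour = "subtype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
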