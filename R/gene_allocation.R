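#' Subtype-versus-rest differential tests
#'
#' For every gene and every subtype, a two-sided Welch two-sample t-test of
#' the subtype's samples against all remaining samples. Genes constant in
#' both groups get `t = 0, p = 1` with a warning.
#'
#' @param mat Numeric matrix (genes x samples); typically the z-normalized
#'   candidate-gene matrix.
#' @param assignment A `subtype_assignment` (or named integer label vector).
#' @return An `allocation_table`: data.frame with columns `gene`, `subtype`,
#'   `t`, `p`, `mean_diff` (subtype mean minus rest mean).
#' @export
differential_t_test <- function(mat, assignment) {
  labels <- assignment_labels(assignment, colnames(mat))
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes")
  small <- subtypes[vapply(subtypes, function(s) sum(labels == s) < 2L, TRUE)]
  if (length(small)) {
    stop("subtype(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  genes <- rownames(mat)
  out <- vector("list", length(subtypes))
  n_degenerate <- 0L
  for (si in seq_along(subtypes)) {
    s <- subtypes[si]
    in_s <- labels == s
    tt <- numeric(length(genes))
    pp <- numeric(length(genes))
    md <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      x <- mat[gi, in_s]
      y <- mat[gi, !in_s]
      md[gi] <- mean(x) - mean(y)
      res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                      error = function(e) NULL)
      if (is.null(res)) {
        tt[gi] <- 0
        pp[gi] <- 1
        n_degenerate <- n_degenerate + 1L
      } else {
        tt[gi] <- unname(res$statistic)
        pp[gi] <- res$p.value
      }
    }
    out[[si]] <- data.frame(gene = genes, subtype = s, t = tt, p = pp,
                            mean_diff = md, stringsAsFactors = FALSE)
  }
  if (n_degenerate) {
    warning(n_degenerate, " gene/subtype pair(s) constant in both groups; ",
            "p set to 1")
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("allocation_table", "data.frame")
  tab
}

assignment_labels <- function(assignment, sample_ids) {
  labels <- if (inherits(assignment, "subtype_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  if (!all(sample_ids %in% names(labels))) {
    stop("samples missing from the subtype assignment: ",
         paste(utils::head(setdiff(sample_ids, names(labels)), 5L),
               collapse = ", "))
  }
  labels[sample_ids]
}

#' Allocate candidate genes to subtypes
#'
#' A gene joins a subtype's set iff its subtype-versus-rest p-value is below
#' `alpha`; a gene may join several subtypes (the sets typically overlap
#' heavily). Among the subtypes where a gene is significant, the one with the
#' largest |t| is flagged `primary`.
#'
#' @param table An `allocation_table` from [differential_t_test()].
#' @param alpha Significance threshold on the (optionally adjusted) p-value.
#' @param adjust `"none"` (raw p, the default) or `"BH"`
#'   (Benjamini-Hochberg within each subtype).
#' @return A `subtype_gene_sets`: list with the flagged `table`, per-subtype
#'   `sets`, the `common` intersection and the `alpha` used.
#' @export
allocate_genes <- function(table, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  tab <- as.data.frame(table)
  tab$p_use <- tab$p
  if (adjust == "BH") {
    for (s in unique(tab$subtype)) {
      idx <- tab$subtype == s
      tab$p_use[idx] <- stats::p.adjust(tab$p[idx], method = "BH")
    }
  }
  tab$allocated <- tab$p_use < alpha
  tab$primary <- FALSE
  for (g in unique(tab$gene[tab$allocated])) {
    idx <- which(tab$gene == g & tab$allocated)
    tab$primary[idx[which.max(abs(tab$t[idx]))]] <- TRUE
  }
  sets <- lapply(split(tab, tab$subtype),
                 function(d) sort(d$gene[d$allocated]))
  names(sets) <- paste0("subtype", names(sets))
  primary_sets <- lapply(split(tab, tab$subtype),
                         function(d) sort(d$gene[d$primary]))
  names(primary_sets) <- names(sets)
  common <- if (length(sets) >= 2L) Reduce(intersect, sets) else sets[[1L]]
  structure(list(table = tab, sets = sets, primary_sets = primary_sets,
                 common = common, alpha = alpha),
            class = "subtype_gene_sets")
}

#' Intersect per-subtype gene sets
#'
#' @param sets A `subtype_gene_sets` or plain list of >= 2 character vectors.
#' @return Character vector: genes common to every subtype set.
#' @export
intersect_gene_sets <- function(sets) {
  lst <- if (inherits(sets, "subtype_gene_sets")) sets$sets else sets
  if (length(lst) < 2L) stop("need at least 2 subtype gene sets")
  sort(Reduce(intersect, lst))
}

#' Write an allocation table as TSV
#'
#' @param allocation A `subtype_gene_sets` from [allocate_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation_table <- function(allocation, path) {
  tab <- allocation$table
  utils::write.table(
    tab[, c("gene", "subtype", "t", "p", "mean_diff", "allocated", "primary")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
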