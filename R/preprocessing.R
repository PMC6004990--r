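#' Collapse probe-level rows to gene symbols
#'
#' Each gene's expression is the arithmetic mean of the rows of all probes
#' annotated to it. Probes mapping to several symbols contribute to each;
#' probes absent from the annotation are dropped with a message.
#'
#' @param mat Numeric matrix keyed by probe ids (rows).
#' @param annotation data.frame with columns `probe_id` and `gene_symbol`.
#' @return Numeric matrix with one row per gene symbol; sample columns
#'   unchanged and in the original order.
#' @export
collapse_probes <- function(mat, annotation) {
  if (!all(c("probe_id", "gene_symbol") %in% colnames(annotation))) {
    stop("annotation must have columns 'probe_id' and 'gene_symbol'")
  }
  ann <- unique(annotation[, c("probe_id", "gene_symbol")])
  ann <- ann[ann$probe_id %in% rownames(mat), , drop = FALSE]
  if (!nrow(ann)) stop("no probes shared between matrix and annotation")
  n_unann <- sum(!(rownames(mat) %in% ann$probe_id))
  if (n_unann) message(n_unann, " unannotated probe(s) dropped")
  sub <- mat[ann$probe_id, , drop = FALSE]
  sums <- rowsum(sub, group = ann$gene_symbol)
  counts <- as.vector(table(ann$gene_symbol)[rownames(sums)])
  sums / counts
}

#' Z-normalize each gene row
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1
#' (n-1 denominator). Zero-variance rows cannot be scaled and are dropped.
#'
#' @param mat Numeric matrix, genes in rows.
#' @return List with `matrix` (normalized rows) and `report`, a data.frame of
#'   per-gene pre-normalization mean, sd and a dropped flag.
#' @export
zscore_rows <- function(mat) {
  if (ncol(mat) < 2L) stop("z-normalization needs at least 2 samples")
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  drop <- !is.finite(s) | s == 0
  if (all(drop)) stop("all rows have zero variance; nothing to normalize")
  if (any(drop)) {
    message(sum(drop), " zero-variance row(s) dropped: ",
            paste(utils::head(rownames(mat)[drop], 5L), collapse = ", "))
  }
  report <- data.frame(gene = rownames(mat), mean = mu, sd = s,
                       dropped = drop, row.names = NULL,
                       stringsAsFactors = FALSE)
  z <- (mat[!drop, , drop = FALSE] - mu[!drop]) / s[!drop]
  list(matrix = z, report = report)
}

#' Restrict an expression matrix to candidate genes
#'
#' @param mat Numeric matrix, genes in rows.
#' @param candidates Character vector of gene symbols (case-sensitive match).
#' @return The matrix restricted to candidates found; absent candidates are
#'   counted in a message. Fewer than 2 matches is an error.
#' @export
subset_to_candidates <- function(mat, candidates) {
  present <- intersect(candidates, rownames(mat))
  if (length(present) < 2L) {
    stop("fewer than 2 candidate genes present in the expression matrix (",
         length(present), " found)")
  }
  missing <- setdiff(candidates, rownames(mat))
  if (length(missing)) {
    message(length(missing), " candidate gene(s) absent from the matrix")
  }
  mat[present, , drop = FALSE]
}
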