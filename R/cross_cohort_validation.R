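#' Restrict two cohorts to their shared gene universe
#'
#' Both matrices are restricted to the shared gene symbols in identical
#' order; the validation matrix is re-z-normalized within its own cohort so
#' both live on the same working scale despite platform differences.
#'
#' @param discovery Numeric matrix (genes x samples), already normalized.
#' @param validation Numeric matrix (genes x samples) from the independent
#'   cohort.
#' @return List with `discovery` and `validation` matrices on the shared
#'   genes.
#' @export
harmonize_features <- function(discovery, validation) {
  shared <- intersect(rownames(discovery), rownames(validation))
  if (length(shared) < 2L) {
    stop("fewer than 2 genes shared between the cohorts")
  }
  val <- zscore_rows(validation[shared, , drop = FALSE])$matrix
  shared <- intersect(shared, rownames(val))  # zero-variance rows dropped
  if (length(shared) < 2L) {
    stop("fewer than 2 usable shared genes after re-normalization")
  }
  list(discovery = discovery[shared, , drop = FALSE],
       validation = val[shared, , drop = FALSE])
}

#' Confusion matrix of predicted versus clustered labels
#'
#' Rows are the model's predicted classes, columns the independent
#' clustering's classes. With `match = TRUE` the cluster labels are first
#' relabeled by the permutation that maximizes the diagonal (exhaustive
#' assignment search, exact for the small class counts used here), since
#' cluster numbering is arbitrary.
#'
#' @param cluster_labels Named vector: sample -> cluster class.
#' @param predicted_labels Named vector: sample -> predicted class; must
#'   cover the same samples.
#' @param match Relabel clusters to maximize the diagonal (default TRUE).
#' @return A `confusion_matrix`: list with `counts`, `column_totals`,
#'   `ratios` (per-column consistency, percent, 1 decimal), `grand_total`
#'   and the cluster `mapping` applied.
#' @export
build_confusion_matrix <- function(cluster_labels, predicted_labels,
                                   match = TRUE) {
  if (!setequal(names(cluster_labels), names(predicted_labels))) {
    diff <- c(setdiff(names(cluster_labels), names(predicted_labels)),
              setdiff(names(predicted_labels), names(cluster_labels)))
    stop("sample sets differ between the label maps: ",
         paste(utils::head(diff, 5L), collapse = ", "))
  }
  cl <- cluster_labels[names(predicted_labels)]
  classes <- sort(unique(c(cl, predicted_labels)))
  counts <- table(factor(predicted_labels, levels = classes),
                  factor(cl, levels = classes))
  counts <- unclass(counts)
  dimnames(counts) <- list(predicted = as.character(classes),
                           cluster = as.character(classes))
  # mapping: cluster class -> the model class it was matched to
  mapping <- stats::setNames(classes, as.character(classes))
  if (match && length(classes) >= 2L) {
    perm <- best_diagonal_permutation(counts)
    counts <- counts[, perm, drop = FALSE]
    mapping <- stats::setNames(classes[order(perm)], as.character(classes))
    message("cluster-to-model matching: cluster ",
            paste(colnames(counts), collapse = ","), " -> model ",
            paste(rownames(counts), collapse = ","))
  }
  as_confusion_matrix(counts, mapping = mapping)
}

#' Build a confusion matrix from a counts table
#'
#' For count tables obtained elsewhere (e.g. published validation results):
#' computes column totals, per-column consistency ratios and the grand
#' total.
#'
#' @param counts Square nonnegative integer matrix, predicted classes in
#'   rows, cluster classes in columns.
#' @param mapping Optional record of the cluster relabeling applied.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, mapping = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts,
                 column_totals = colSums(counts),
                 ratios = consistency_ratios_from_counts(counts),
                 grand_total = sum(counts),
                 mapping = mapping),
            class = "confusion_matrix")
}

# Exhaustive search over column permutations maximizing the diagonal sum.
best_diagonal_permutation <- function(counts) {
  k <- ncol(counts)
  if (k > 8L) stop("exhaustive label matching supports at most 8 classes")
  perms <- all_permutations(k)
  diag_sum <- vapply(seq_len(nrow(perms)), function(i) {
    sum(diag(counts[, perms[i, ], drop = FALSE]))
  }, 0)
  perms[which.max(diag_sum), ]
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Per-class consistency ratios
#'
#' ratio(c) = diagonal count / column total, as a percentage rounded to one
#' decimal.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector of percentages.
#' @export
consistency_ratios <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  consistency_ratios_from_counts(cm$counts)
}

consistency_ratios_from_counts <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("zero column total for class(es): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  round(100 * diag(counts) / tot, 1)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Predicted (rows) vs clustered (columns), n =", x$grand_total, "\n")
  m <- rbind(x$counts, Total = x$column_totals,
             `Ratio (%)` = x$ratios)
  print(m)
  invisible(x)
}

#' Write a confusion matrix as TSV (with Total and Ratio rows)
#'
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path) {
  m <- rbind(cm$counts, Total = cm$column_totals, Ratio = cm$ratios)
  df <- data.frame(class = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Permutation significance of per-class consistency ratios
#'
#' The null distribution is built by uniformly permuting the predicted
#' labels across samples (preserving both marginal distributions); per class
#' the p-value is `(1 + #{permuted ratio >= observed}) / (n_permutations +
#' 1)`, so it is always at least `1 / (n_permutations + 1)`. A
#' resample-with-replacement mode of the predicted labels is provided as an
#' alternative null.
#'
#' @inheritParams build_confusion_matrix
#' @param n_permutations Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @param scheme `"permute"` (default) or `"resample"`.
#' @return A `permutation_result`: data.frame per class with
#'   `observed_ratio`, `p`, plus attributes `n_permutations`, `seed`,
#'   `scheme`.
#' @export
permutation_significance <- function(cluster_labels, predicted_labels,
                                     n_permutations = 10000L, seed = 1L,
                                     scheme = c("permute", "resample")) {
  scheme <- match.arg(scheme)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  cm <- suppressMessages(
    build_confusion_matrix(cluster_labels, predicted_labels, match = FALSE))
  observed <- cm$ratios
  cl <- factor(cluster_labels[names(predicted_labels)],
               levels = rownames(cm$counts))
  pr <- factor(predicted_labels, levels = rownames(cm$counts))
  k <- nlevels(cl)
  set.seed(seed)
  exceed <- numeric(k)
  pr_int <- as.integer(pr)
  cl_int <- as.integer(cl)
  col_tot <- tabulate(cl_int, k)
  n <- length(pr_int)
  for (b in seq_len(n_permutations)) {
    perm <- if (scheme == "permute") sample(pr_int) else
      sample(pr_int, n, replace = TRUE)
    diag_cnt <- tabulate(cl_int[perm == cl_int], k)
    ratio <- round(100 * diag_cnt / col_tot, 1)
    exceed <- exceed + (ratio >= observed)
  }
  p <- (1 + exceed) / (n_permutations + 1)
  out <- data.frame(class = rownames(cm$counts),
                    observed_ratio = unname(observed), p = unname(p),
                    stringsAsFactors = FALSE)
  structure(out, class = c("permutation_result", "data.frame"),
            n_permutations = n_permutations, seed = seed, scheme = scheme)
}
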