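#' Per-sample pathway deviation features
#'
#' The per-sample analog of the pathway deviation score: for pathway feature
#' P with usable genes i and reference means `Ybar_i`, sample s gets
#' `d_s(P) = (1/N) * sum_i (x_is - Ybar_i)^2`. Averaging these over a
#' subtype's samples does not in general equal the subtype-level score
#' (Jensen gap): the squared deviation of a mean is at most the mean squared
#' deviation.
#'
#' @param mat Numeric matrix (genes x samples).
#' @param pathway_gene_lists Named list: feature id -> gene set (for subtype
#'   prediction typically one feature per scored pathway/subtype pair, see
#'   [deviation_feature_schema()]).
#' @param reference_means Named numeric vector of per-gene reference means
#'   (cohort means of the discovery matrix).
#' @return A `sample_features`: list with `features` (samples x features
#'   matrix) and `schema` (the gene lists and reference means actually used,
#'   for reuse on new cohorts).
#' @export
sample_deviation_features <- function(mat, pathway_gene_lists,
                                      reference_means) {
  usable <- list()
  cols <- list()
  for (fid in names(pathway_gene_lists)) {
    genes <- intersect(intersect(pathway_gene_lists[[fid]], rownames(mat)),
                       names(reference_means))
    if (!length(genes)) {
      warning("feature '", fid, "' has no usable genes; column skipped")
      next
    }
    dev2 <- (mat[genes, , drop = FALSE] - reference_means[genes])^2
    cols[[fid]] <- colMeans(dev2)
    usable[[fid]] <- genes
  }
  if (!length(cols)) stop("no feature had usable genes")
  features <- do.call(cbind, cols)
  rownames(features) <- colnames(mat)
  structure(list(features = features,
                 schema = list(pathway_genes = usable,
                               reference_means = reference_means[
                                 unique(unlist(usable, use.names = FALSE))])),
            class = "sample_features")
}

#' Feature schema from a deviation-score table
#'
#' One feature per scored (pathway, subtype) pair, whose gene list is the
#' pathway's intersection with that subtype's gene set. Allocated gene sets
#' overlap heavily across subtypes, which would make the per-subtype feature
#' columns nearly identical; the primary sets (each gene counted only where
#' its differential signal is strongest) keep the features subtype-specific,
#' so they are the recommended input. Pairs with an empty intersection are
#' dropped.
#'
#' @param pathways A `gene_sets` collection.
#' @param subtype_sets Named list of per-subtype gene sets, one per subtype
#'   in sorted label order (typically `allocate_genes(...)$primary_sets`).
#' @param dev_table data.frame from [deviation_score_table()].
#' @return Named list of gene sets, names `pathway|subtype`.
#' @export
deviation_feature_schema <- function(pathways, subtype_sets, dev_table) {
  out <- list()
  subtypes <- sort(unique(dev_table$subtype))
  for (r in seq_len(nrow(dev_table))) {
    pid <- dev_table$pathway[r]
    s <- dev_table$subtype[r]
    si <- match(s, subtypes)
    genes <- intersect(pathways[[pid]], subtype_sets[[si]])
    if (length(genes)) out[[paste0(pid, "|", s)]] <- genes
  }
  if (!length(out)) stop("no (pathway, subtype) pair has usable genes")
  out
}

#' Train one-vs-rest linear SVM subtype models
#'
#' One soft-margin linear SVM per subtype (penalty `C`, default 1), each
#' separating that subtype from all others. The fitted models are reduced to
#' explicit weight vectors and biases, so decision scores are plain linear
#' functions of the features and the model serializes to JSON.
#'
#' @param features A `sample_features` (or plain samples x features matrix).
#' @param labels A `subtype_assignment` or named label vector covering the
#'   feature rows.
#' @param C Soft-margin penalty (> 0).
#' @return An `svm_subtype_model`: list with `weights` (features x classes),
#'   `biases`, `classes`, `C` and the feature `schema`.
#' @export
train_classifier <- function(features, labels, C = 1) {
  X <- feature_matrix(features)
  y <- assignment_labels(labels, rownames(X))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  cnt <- table(y)
  if (any(cnt < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  W <- matrix(0, ncol(X), length(classes),
              dimnames = list(colnames(X), paste0("class", classes)))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    yy <- factor(ifelse(y == classes[ci], "pos", "rest"),
                 levels = c("pos", "rest"))
    fit <- e1071::svm(X, yy, kernel = "linear", cost = C, scale = FALSE)
    w <- t(fit$coefs) %*% fit$SV
    # e1071 signs decision values by its internal class ordering; orient so
    # that the positive class always scores positive.
    flip <- if (fit$labels[1L] == which(levels(yy) == "pos")) 1 else -1
    W[, ci] <- flip * as.numeric(w)
    b[ci] <- flip * (-fit$rho)
  }
  structure(list(weights = W, biases = b, classes = classes, C = C,
                 schema = feature_schema(features)),
            class = "svm_subtype_model")
}

feature_matrix <- function(features) {
  if (inherits(features, "sample_features")) features$features
  else as.matrix(features)
}

feature_schema <- function(features) {
  if (inherits(features, "sample_features")) features$schema else NULL
}

#' Per-class decision scores
#'
#' @param model An `svm_subtype_model`.
#' @param features A `sample_features` or matrix with the model's feature
#'   columns.
#' @return Numeric matrix, samples x classes.
#' @export
decision_scores <- function(model, features) {
  X <- feature_matrix(features)
  missing <- setdiff(rownames(model$weights), colnames(X))
  if (length(missing)) {
    stop("feature schema mismatch; missing feature column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  X <- X[, rownames(model$weights), drop = FALSE]
  S <- X %*% model$weights
  sweep(S, 2L, model$biases, `+`)
}

#' Predict subtype labels
#'
#' Label = argmax of the per-class decision scores; exact ties go to the
#' lower-numbered subtype.
#'
#' @inheritParams decision_scores
#' @return Named integer vector of predicted labels.
#' @export
predict_labels <- function(model, features) {
  S <- decision_scores(model, features)
  idx <- apply(S, 1L, which.max)  # which.max takes the first (lowest) on ties
  out <- model$classes[idx]
  names(out) <- rownames(S)
  out
}

#' Stratified cross-validated ROC/AUC per subtype
#'
#' Stratified fold assignment, one-vs-rest linear SVMs refit per fold,
#' out-of-fold decision scores pooled per subtype, then ROC/AUC on the pooled
#' scores. Fully reproducible given `seed`.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (default 5); must not exceed the smallest
#'   class size.
#' @param seed Integer seed for the fold assignment.
#' @return A `cv_result`: per class `roc` (data.frame fpr/tpr), `auc` and
#'   `accuracy` (pooled out-of-fold one-vs-rest accuracy at threshold 0);
#'   plus `overall_accuracy` (argmax rule), `fold_assignment` and `seed`.
#' @export
cross_validate_roc <- function(features, labels, folds = 5L, seed = 1L,
                               C = 1) {
  X <- feature_matrix(features)
  y <- assignment_labels(labels, rownames(X))
  classes <- sort(unique(y))
  cnt <- table(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > min(cnt)) {
    stop("folds (", folds, ") exceeds the smallest class size (", min(cnt), ")")
  }
  set.seed(seed)
  fold <- integer(length(y))
  names(fold) <- rownames(X)
  for (cl in classes) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(rownames(X), paste0("class", classes)))
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- train_classifier(X[!test, , drop = FALSE], y[!test], C = C)
    scores[test, ] <- decision_scores(fit, X[test, , drop = FALSE])
  }
  per_class <- lapply(seq_along(classes), function(ci) {
    pos <- y == classes[ci]
    r <- pROC::roc(response = factor(ifelse(pos, "pos", "neg"),
                                     levels = c("neg", "pos")),
                   predictor = scores[, ci], direction = "<", quiet = TRUE)
    roc_df <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
    roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), , drop = FALSE]
    rownames(roc_df) <- NULL
    list(class = classes[ci], roc = roc_df, auc = as.numeric(pROC::auc(r)),
         accuracy = mean((scores[, ci] > 0) == pos))
  })
  names(per_class) <- paste0("subtype", classes)
  pred <- classes[apply(scores, 1L, which.max)]
  structure(list(per_class = per_class,
                 overall_accuracy = mean(pred == y),
                 fold_assignment = fold, seed = seed, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated one-vs-rest SVM (", x$folds, "-fold, seed ", x$seed,
      ")\n", sep = "")
  for (pc in x$per_class) {
    cat("  subtype ", pc$class, ": AUC = ", round(pc$auc, 3),
        ", accuracy = ", round(pc$accuracy, 3), "\n", sep = "")
  }
  cat("  overall argmax accuracy = ", round(x$overall_accuracy, 3), "\n",
      sep = "")
  invisible(x)
}

#' Serialize / restore an SVM subtype model as JSON
#'
#' @param model An `svm_subtype_model`.
#' @param path Output path.
#' @return `path` invisibly; `load_svm_model()` returns the restored model.
#' @export
save_svm_model <- function(model, path) {
  obj <- list(format = "copdsubtype-svm", version = 1L,
              classes = model$classes, C = model$C,
              feature_names = rownames(model$weights),
              weights = unclass(model$weights), biases = model$biases,
              schema = model$schema)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_svm_model
#' @export
load_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "copdsubtype-svm") {
    stop("not a serialized svm_subtype_model: ", path)
  }
  W <- as.matrix(obj$weights)
  dimnames(W) <- list(obj$feature_names, paste0("class", obj$classes))
  schema <- obj$schema
  if (!is.null(schema)) {
    schema$reference_means <- unlist(schema$reference_means)
    schema$pathway_genes <- lapply(schema$pathway_genes, unlist)
  }
  structure(list(weights = W, biases = as.numeric(obj$biases),
                 classes = as.integer(obj$classes), C = obj$C,
                 schema = schema),
            class = "svm_subtype_model")
}

#' Plot cross-validated ROC curves
#'
#' @param cv A `cv_result`.
#' @return A ggplot object with one curve per subtype, AUC in the legend.
#' @export
plot_roc_curves <- function(cv) {
  dfs <- do.call(rbind, lapply(cv$per_class, function(pc) {
    d <- pc$roc
    d$subtype <- sprintf("subtype %s (AUC %.2f)", pc$class, pc$auc)
    d
  }))
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$subtype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
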