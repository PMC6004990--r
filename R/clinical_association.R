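#' Test a continuous clinical variable across subtypes
#'
#' One-way fixed-effects ANOVA of the variable across the k subtypes.
#' Missing values are dropped per-variable with a message.
#'
#' @param clinical data.frame as from [read_clinical_table()].
#' @param assignment A `subtype_assignment` (or named label vector).
#' @param variable One of `"FEV1"`, `"FEV1_FVC"`, `"age"`.
#' @return An `association_result`: list with `variable`, `test`,
#'   `statistic` (F), `df`, `p` and a per-subtype `summary` data.frame
#'   (n, mean, sd).
#' @export
continuous_association <- function(clinical, assignment,
                                   variable = c("FEV1", "FEV1_FVC", "age")) {
  variable <- match.arg(variable)
  if (!variable %in% colnames(clinical)) {
    stop("clinical table has no column '", variable, "'")
  }
  labels <- assignment_labels(assignment, clinical$sample_id)
  value <- clinical[[variable]]
  keep <- !is.na(value) & !is.na(labels)
  if (any(!keep)) message(sum(!keep), " sample(s) with missing ", variable,
                          " dropped")
  value <- value[keep]
  grp <- factor(labels[keep])
  cnt <- table(grp)
  if (any(cnt < 2)) {
    stop("subtype(s) with fewer than 2 non-missing values for ", variable,
         ": ", paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  fit <- stats::aov(value ~ grp)
  sm <- summary(fit)[[1L]]
  per <- do.call(rbind, lapply(levels(grp), function(l) {
    v <- value[grp == l]
    data.frame(subtype = l, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  structure(list(variable = variable, test = "one-way ANOVA",
                 statistic = sm[["F value"]][1L],
                 df = c(sm[["Df"]][1L], sm[["Df"]][2L]),
                 p = sm[["Pr(>F)"]][1L], summary = per),
            class = "association_result")
}

#' Test a categorical clinical variable across subtypes
#'
#' Default is the chi-square test of independence on the subtype-by-category
#' contingency table (no continuity correction); `method = "anova"` instead
#' runs one-way ANOVA on a 0/1 coding of a binary variable, as a strict
#' replication mode.
#'
#' @param clinical data.frame as from [read_clinical_table()].
#' @param assignment A `subtype_assignment` (or named label vector).
#' @param variable Column name; default `"sex"`.
#' @param method `"chisq"` (default) or `"anova"`.
#' @return An `association_result`; for chi-square the per-subtype `summary`
#'   holds observed counts and the result carries `expected` counts.
#' @export
categorical_association <- function(clinical, assignment, variable = "sex",
                                    method = c("chisq", "anova")) {
  method <- match.arg(method)
  if (!variable %in% colnames(clinical)) {
    stop("clinical table has no column '", variable, "'")
  }
  labels <- assignment_labels(assignment, clinical$sample_id)
  value <- clinical[[variable]]
  keep <- !is.na(value) & !is.na(labels)
  if (any(!keep)) message(sum(!keep), " sample(s) with missing ", variable,
                          " dropped")
  value <- value[keep]
  grp <- factor(labels[keep])
  if (method == "anova") {
    lv <- sort(unique(value))
    if (length(lv) != 2L) stop("ANOVA coding needs a binary variable")
    clin2 <- data.frame(sample_id = clinical$sample_id[keep],
                        code = as.numeric(value == lv[2L]))
    colnames(clin2)[2L] <- "FEV1"  # reuse the continuous path on the coding
    res <- continuous_association(clin2, labels[keep], "FEV1")
    res$variable <- variable
    res$test <- paste0("one-way ANOVA on 0/1 coding (1 = ", lv[2L], ")")
    return(res)
  }
  tab <- table(subtype = grp, value = factor(value))
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in the contingency table; merge categories first")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  per <- as.data.frame.matrix(tab)
  per <- cbind(data.frame(subtype = rownames(per), stringsAsFactors = FALSE),
               per)
  rownames(per) <- NULL
  structure(list(variable = variable, test = "chi-square (no correction)",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 summary = per, expected = ct$expected),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(x$variable, " ~ subtype: ", x$test, "\n", sep = "")
  cat("  statistic = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the standard clinical association battery
#'
#' FEV1, FEV1/FVC and age by ANOVA; sex by chi-square.
#'
#' @inheritParams continuous_association
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p`.
#' @export
clinical_association_table <- function(clinical, assignment) {
  res <- list(
    continuous_association(clinical, assignment, "FEV1"),
    continuous_association(clinical, assignment, "FEV1_FVC"),
    continuous_association(clinical, assignment, "age"),
    categorical_association(clinical, assignment, "sex")
  )
  do.call(rbind, lapply(res, function(r) {
    data.frame(variable = r$variable, test = r$test, statistic = r$statistic,
               p = r$p, stringsAsFactors = FALSE)
  }))
}
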