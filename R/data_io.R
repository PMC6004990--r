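#' Read a gene-by-sample expression table
#'
#' Reads a delimited text file with a header row of sample identifiers and a
#' first column of gene (or probe) identifiers. The delimiter is detected from
#' the header line and restricted to TAB or comma.
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric matrix, genes in rows, samples in columns, with dimnames.
#'   Duplicate row identifiers are an error: probe-level tables must go
#'   through [collapse_probes()] before gene-level analysis.
#' @export
read_expression_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) {
    stop("expression table needs an id column plus at least one sample column: ", path)
  }
  ids <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]  # before `[.data.frame` mangles duplicates
  vals <- df[, -1L, drop = FALSE]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate row ids (e.g. '", ids[duplicated(ids)][1L],
         "') in ", path,
         "; collapse probe-level rows with collapse_probes() first")
  }
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & !(toupper(trimws(col)) %in% c("NA", "NAN")))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                     col[bad[1L]], ids[bad[1L]], samples[j], path))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(ids, samples)
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, id_name = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `gene_sets` object: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_sets(list(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT parse error at line ", which(nf < 3L)[1L],
         " of ", path, ": fewer than 3 tab-separated fields")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(seq_along(parts), function(i) {
    g <- parts[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("duplicate members in gene set '", ids[i], "' deduplicated")
      g <- unique(g)
    }
    g
  })
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s) in ", path, ": ",
         paste(ids[lengths(sets) == 0L], collapse = ", "))
  }
  names(sets) <- ids
  names(desc) <- ids
  gene_sets(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique members enforced).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(lapply(sets, unique), class = "gene_sets",
            descriptions = descriptions)
}

#' Write gene sets in GMT format
#'
#' @param sets A `gene_sets` object or named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample clinical table
#'
#' Expects a delimited file with a header containing a sample identifier
#' column and the columns FEV1, FEV1/FVC, age and sex (matched
#' case-insensitively; `gender` is accepted for sex). Extra columns are
#' preserved. Sex tokens are normalized to `male`/`female`.
#'
#' @param path Path to a TSV/CSV file.
#' @return data.frame with columns `sample_id`, `FEV1`, `FEV1_FVC`, `age`,
#'   `sex` plus any extra columns.
#' @export
read_clinical_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  norm <- tolower(gsub("[^A-Za-z0-9]+", "_", colnames(df)))
  pick <- function(cands, what) {
    hit <- which(norm %in% cands)
    if (!length(hit)) stop("clinical table missing required column: ", what)
    hit[1L]
  }
  i_id <- pick(c("sample_id", "sample", "id"), "sample id")
  i_fev1 <- pick(c("fev1"), "FEV1")
  i_ratio <- pick(c("fev1_fvc", "fev1fvc"), "FEV1/FVC")
  i_age <- pick(c("age"), "age")
  i_sex <- pick(c("sex", "gender"), "sex")
  as_num_checked <- function(x, what) {
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & nzchar(trimws(x)) &
                   toupper(trimws(x)) != "NA")
    if (length(bad)) {
      stop("non-numeric ", what, " value '", x[bad[1L]], "' in ", path)
    }
    num
  }
  out <- data.frame(
    sample_id = as.character(df[[i_id]]),
    FEV1 = as_num_checked(df[[i_fev1]], "FEV1"),
    FEV1_FVC = as_num_checked(df[[i_ratio]], "FEV1/FVC"),
    age = as_num_checked(df[[i_age]], "age"),
    sex = normalize_sex(df[[i_sex]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample ids in clinical table: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  if (any(out$FEV1_FVC < 0, na.rm = TRUE)) stop("FEV1/FVC must be >= 0")
  if (any(out$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  extra <- setdiff(seq_along(df), c(i_id, i_fev1, i_ratio, i_age, i_sex))
  if (length(extra)) out <- cbind(out, df[, extra, drop = FALSE])
  out
}

normalize_sex <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- ifelse(tok %in% c("m", "male"), "male",
                ifelse(tok %in% c("f", "female"), "female", NA_character_))
  bad <- which(is.na(out) & !is.na(tok) & nzchar(tok) & tok != "na")
  if (length(bad)) {
    stop("unknown sex token '", x[bad[1L]], "' (expected male/female/M/F)")
  }
  out
}

#' Write a clinical table as TSV
#'
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate gene list
#'
#' Plain text, one symbol per line; `#` starts a comment; blank lines ignored.
#' Symbols are matched case-sensitively throughout the package.
#'
#' @param path Path to the gene list.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  if (anyDuplicated(x)) {
    warning(sum(duplicated(x)), " duplicate symbols in ", path, " dropped")
    x <- unique(x)
  }
  x
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  if (grepl("\t", first, fixed = TRUE)) "\t"
  else if (grepl(",", first, fixed = TRUE)) ","
  else stop("cannot detect delimiter (TAB or comma) in ", path)
}
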