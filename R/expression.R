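#' Construct an expression dataset
#'
#' Wraps a patients x features numeric matrix together with unique patient
#' and feature identifiers.  The same container holds either a gene or a
#' miRNA expression layer; rows are patients, columns are features.
#'
#' @param values Numeric matrix, patients in rows, features in columns.
#'   No missing values are allowed.
#' @param patient_ids Character vector of unique patient identifiers, one
#'   per row.  Defaults to `rownames(values)`.
#' @param feature_ids Character vector of unique feature identifiers, one
#'   per column.  Defaults to `colnames(values)`.
#' @return An object of class `expression_dataset`: the matrix with row and
#'   column names set to the identifiers.
#' @examples
#' x <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("g1", "g2", "g3")))
#' expression_dataset(x)
#' @export
expression_dataset <- function(values, patient_ids = rownames(values),
                               feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_arg("expression values must be numeric")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_arg("expression values contain missing or non-finite entries")
  }
  if (is.null(patient_ids) || length(patient_ids) != nrow(values)) {
    stop_arg("patient_ids must match the number of rows (%d)", nrow(values))
  }
  if (is.null(feature_ids) || length(feature_ids) != ncol(values)) {
    stop_arg("feature_ids must match the number of columns (%d)", ncol(values))
  }
  patient_ids <- as.character(patient_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(patient_ids)) stop_arg("patient_ids must be unique")
  if (anyDuplicated(feature_ids)) stop_arg("feature_ids must be unique")
  dimnames(values) <- list(patient_ids, feature_ids)
  structure(values, class = c("expression_dataset", "matrix", "array"))
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d patients x %d features\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname expression_dataset
#' @param x Object to test or print.
#' @export
is_expression_dataset <- function(x) inherits(x, "expression_dataset")

as_expr <- function(x, what = "data") {
  if (is_expression_dataset(x)) return(x)
  if (is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x))) {
    return(expression_dataset(x))
  }
  stop_arg("%s must be an expression_dataset (or a named numeric matrix)", what)
}

# Subset features, preserving class and order of `ids`.
select_features <- function(data, ids) {
  missing <- setdiff(ids, colnames(data))
  if (length(missing)) {
    stop_arg("unknown feature id(s): %s", paste(missing, collapse = ", "))
  }
  expression_dataset(unclass(data)[, ids, drop = FALSE])
}

check_same_patients <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    stop_arg("datasets must share an identical ordered patient list")
  }
  invisible(TRUE)
}

#' Read and write expression matrices
#'
#' Tab-separated layout: header row of feature identifiers, first column of
#' patient identifiers, numeric entries elsewhere.
#'
#' @param path Path to a TSV file.
#' @return `read_expression()` returns an [expression_dataset].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_arg("expression file %s has no feature columns", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  expression_dataset(m, patient_ids = ids, feature_ids = colnames(df)[-1])
}

#' @rdname read_expression
#' @param data An [expression_dataset].
#' @export
write_expression <- function(data, path) {
  data <- as_expr(data)
  df <- data.frame(patient_id = rownames(data), unclass(data),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a patient label vector
#'
#' Labels live in \{-1, 0, +1\}: -1 and +1 are the two clinical outcome
#' classes (e.g. short-term versus long-term survival) and 0 marks an
#' unlabeled patient whose outcome is to be predicted.
#'
#' @param values Numeric vector over \{-1, 0, 1\}.
#' @param patient_ids Character vector of unique patient identifiers;
#'   defaults to `names(values)`.
#' @return A named numeric vector of class `label_vector`.
#' @export
label_vector <- function(values, patient_ids = names(values)) {
  force(patient_ids)
  values <- as.numeric(values)
  if (!all(values %in% c(-1, 0, 1))) {
    stop_arg("labels must lie in {-1, 0, 1}")
  }
  if (is.null(patient_ids) || length(patient_ids) != length(values)) {
    stop_arg("patient_ids must match the number of labels")
  }
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop_arg("patient_ids must be unique")
  names(values) <- patient_ids
  structure(values, class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label_vector: %d patients (%d labeled +1, %d labeled -1, %d unlabeled)\n",
              length(x), sum(x == 1), sum(x == -1), sum(x == 0)))
  invisible(x)
}

#' @rdname label_vector
#' @param path Path to a labels TSV with columns `patient_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(df))) {
    stop_arg("labels file %s must have columns patient_id, label", path)
  }
  label_vector(df$label, df$patient_id)
}

#' @rdname label_vector
#' @param labels A `label_vector`.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(patient_id = names(labels), label = as.numeric(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
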