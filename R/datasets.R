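#' Discrete dataset container
#'
#' An N x n matrix of 0-based categorical state indices with per-column
#' cardinalities; the raw material from which the K2 counts are tabulated.
#'
#' @param values integer matrix (rows = samples), entries in \code{[0, r_i)}.
#' @param columns character vector of variable names.
#' @param cardinalities integer vector of state counts per column; defaults
#'   to \code{max(column) + 1} but at least 2.
#' @return object of class \code{discrete_dataset}.
#' @export
discrete_dataset <- function(values, columns = colnames(values),
                             cardinalities = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(columns)) columns <- paste0("X", seq_len(ncol(values)))
  columns <- as.character(columns)
  if (length(columns) != ncol(values)) stop("column name length mismatch")
  if (nrow(values) < 1L) stop("dataset needs at least one row")
  if (is.null(cardinalities)) {
    cardinalities <- pmax(2L, apply(values, 2L, max) + 1L)
  }
  cardinalities <- as.integer(cardinalities)
  names(cardinalities) <- columns
  for (j in seq_along(columns)) {
    v <- values[, j]
    if (any(v < 0L) || any(v >= cardinalities[[j]])) {
      stop("states of ", columns[[j]], " outside [0, ", cardinalities[[j]], ")")
    }
  }
  colnames(values) <- columns
  structure(list(columns = columns, values = values,
                 cardinalities = cardinalities),
            class = "discrete_dataset")
}

#' Continuous dataset container
#'
#' @param values numeric matrix (rows = samples), finite entries.
#' @param columns character vector of variable names.
#' @return object of class \code{continuous_dataset}.
#' @export
continuous_dataset <- function(values, columns = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(columns)) columns <- paste0("X", seq_len(ncol(values)))
  columns <- as.character(columns)
  if (length(columns) != ncol(values)) stop("column name length mismatch")
  if (nrow(values) < 1L) stop("dataset needs at least one row")
  if (!all(is.finite(values))) stop("non-finite entries")
  colnames(values) <- columns
  structure(list(columns = columns, values = values), class = "continuous_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("Discrete dataset: %d samples x %d variables (cardinalities %s)\n",
              nrow(x$values), length(x$columns),
              paste(x$cardinalities, collapse = ",")))
  invisible(x)
}

#' @export
print.continuous_dataset <- function(x, ...) {
  cat(sprintf("Continuous dataset: %d samples x %d variables\n",
              nrow(x$values), length(x$columns)))
  invisible(x)
}

#' Read / write datasets as delimited text
#'
#' Plain CSV/TSV with a header row of variable names; discrete states are
#' written as 0-based integers so files diff bit-exactly.
#'
#' @param path file path.
#' @param sep field separator, \code{","} or \code{"\t"} (inferred from the
#'   file extension by default).
#' @param cardinalities optional per-column state counts for discrete data.
#' @return \code{read_discrete_dataset} a \code{discrete_dataset};
#'   \code{read_continuous_dataset} a \code{continuous_dataset}.
#' @name dataset_io
NULL

infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' @rdname dataset_io
#' @param data dataset object to write.
#' @export
write_dataset <- function(data, path, sep = NULL) {
  sep <- infer_sep(path, sep)
  utils::write.table(data$values, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_discrete_dataset <- function(path, sep = NULL, cardinalities = NULL) {
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  discrete_dataset(as.matrix(df), columns = colnames(df),
                   cardinalities = cardinalities)
}

#' @rdname dataset_io
#' @export
read_continuous_dataset <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  continuous_dataset(as.matrix(df), columns = colnames(df))
}
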