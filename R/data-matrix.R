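#' Read a samples-by-variables data matrix from delimited text
#'
#' Reads a CSV file with one header row into the tabular form used by the
#' rest of the pipeline: a tibble whose first column, `sample_id`, holds the
#' sample labels and whose remaining columns are numeric variables
#' (metabolites, transcripts, ...). An optional first label column in the
#' file is auto-detected (non-numeric first data cell). Empty cells and the
#' tokens `NA` / `NaN` (case-insensitive) become missing values, as does any
#' other cell that does not parse as a number.
#'
#' @param path Path to a delimited text file with a header row.
#' @param orientation `"samples"` if file rows are samples (default) or
#'   `"variables"` if file rows are variables; the returned tibble is always
#'   samples x variables.
#' @param condition Optional free-text condition label attached as the
#'   `"condition"` attribute.
#' @param sep Field separator, default comma.
#' @return A tibble with column `sample_id` followed by one numeric column
#'   per variable.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,Ala,Glc,Cit", "s1,1,4,2", "s2,2,3,1",
#'              "s3,3,NA,4", "s4,4,1,3"), f)
#' read_data_matrix(f)
#' @seealso [as_data_matrix()], [correlate()]
#' @export
read_data_matrix <- function(path,
                             orientation = c("samples", "variables"),
                             condition = NULL,
                             sep = ",") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("empty data matrix in ", path, call. = FALSE)
  }

  # label column present iff the first data cell is non-missing and non-numeric
  first_cell <- raw[1L, 1L]
  has_labels <- is.na(parse_numeric(first_cell)) && !is_missing_token(first_cell)
  if (has_labels) {
    row_ids <- trimws(raw[[1L]])
    values <- raw[, -1L, drop = FALSE]
  } else {
    row_ids <- NULL
    values <- raw
  }
  col_ids <- colnames(values)
  num <- vapply(values, parse_numeric, numeric(nrow(values)))
  num <- matrix(num, nrow = nrow(values),
                dimnames = list(NULL, col_ids))

  if (orientation == "samples") {
    sample_ids <- row_ids %||% paste0("S", seq_len(nrow(num)))
    variable_ids <- col_ids
  } else {
    variable_ids <- row_ids %||% paste0("V", seq_len(nrow(num)))
    sample_ids <- col_ids
    num <- t(num)
  }
  as_data_matrix(num, sample_ids = sample_ids, variable_ids = variable_ids,
                 condition = condition)
}

#' Assemble a data matrix tibble from a numeric matrix
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param sample_ids,variable_ids Optional label vectors; default to the
#'   dimnames of `x` or generated `S1..`/`V1..` labels.
#' @param condition Optional condition label stored as an attribute.
#' @return A validated samples x variables tibble (see [read_data_matrix()]).
#' @export
as_data_matrix <- function(x, sample_ids = NULL, variable_ids = NULL,
                           condition = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  sample_ids <- as.character(sample_ids %||% rownames(x) %||%
                               paste0("S", seq_len(nrow(x))))
  variable_ids <- as.character(variable_ids %||% colnames(x) %||%
                                 paste0("V", seq_len(ncol(x))))
  check_unique(sample_ids, "sample")
  check_unique(variable_ids, "variable")
  if (length(sample_ids) != nrow(x) || length(variable_ids) != ncol(x)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (nrow(x) < 3L) {
    stop("need at least 3 samples, got ", nrow(x), call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop("need at least 2 variables, got ", ncol(x), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(x, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- variable_ids
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
  if (!is.null(condition)) attr(out, "condition") <- condition
  out
}

#' Extract the numeric value matrix from a data matrix tibble
#'
#' Accepts the tibble produced by [read_data_matrix()] (identifier column
#' detected as the first character column), a plain numeric data frame, or a
#' matrix; returns a numeric matrix with sample row names and variable
#' column names.
#'
#' @param data Data matrix in any accepted form.
#' @return Numeric samples x variables matrix.
#' @export
data_matrix_values <- function(data) {
  if (is.matrix(data)) {
    x <- data
    storage.mode(x) <- "double"
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  stopifnot(is.data.frame(data))
  df <- data
  id <- NULL
  if (ncol(df) > 0 && (is.character(df[[1L]]) || is.factor(df[[1L]]))) {
    id <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  rownames(x) <- id %||% paste0("S", seq_len(nrow(x)))
  x
}

parse_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[is_missing_token(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

is_missing_token <- function(x) {
  x <- trimws(as.character(x))
  is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
}

check_unique <- function(ids, axis) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate ", axis, " id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
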