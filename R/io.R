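#' Write the r-table and dual-triangle p-table CSV files
#'
#' Writes the two spreadsheet-ready files of the pipeline:
#' `<prefix>r_table.csv`, the full symmetric correlation matrix with unit
#' diagonal and row/column labels, and `<prefix>p_table.csv`, a square
#' matrix whose strictly-lower triangle holds the raw p-values, whose
#' strictly-upper triangle holds the multiplicity-adjusted p-values, and
#' whose diagonal is 0. Numbers are written with 6 significant digits.
#'
#' @param result A `cn_correlation` object from [correlate()].
#' @param prefix Path prefix for the two files (may be a directory ending in
#'   `/` or any string; the file names `r_table.csv` / `p_table.csv` are
#'   appended).
#' @return Invisibly, the two file paths (named `r` and `p`).
#' @seealso [read_correlation_tables()]
#' @export
write_correlation_tables <- function(result, prefix = "") {
  stopifnot(inherits(result, "cn_correlation"))
  r_path <- paste0(prefix, "r_table.csv")
  p_path <- paste0(prefix, "p_table.csv")

  p <- result$p_raw
  p[upper.tri(p)] <- result$p_adj[upper.tri(p)]
  diag(p) <- 0

  write_labeled_csv(result$r, r_path)
  write_labeled_csv(p, p_path)
  invisible(c(r = r_path, p = p_path))
}

#' Read r-table and dual-triangle p-table CSV files
#'
#' Reconstructs a correlation result from the two files produced by
#' [write_correlation_tables()] (or by any tool following the same
#' convention: raw p below the diagonal, adjusted p above it).
#'
#' @param r_path,p_path Paths to the r-table and p-table CSV files.
#' @return A `cn_correlation` object. `n_pairs`, `method` and
#'   `adjust_method` are not stored in the files and come back as `NA` /
#'   `"unknown"`.
#' @export
read_correlation_tables <- function(r_path, p_path) {
  r <- read_labeled_csv(r_path)
  p <- read_labeled_csv(p_path)
  if (!identical(rownames(r), rownames(p)) ||
      !identical(colnames(r), colnames(p))) {
    stop("variable labels differ between ", r_path, " and ", p_path,
         call. = FALSE)
  }
  if (!identical(rownames(r), colnames(r))) {
    stop("row and column labels differ in ", r_path, call. = FALSE)
  }
  asym <- max(abs(r - t(r)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-6) {
    stop("correlation matrix is not symmetric (max |r - t(r)| = ",
         format(asym), ")", call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-6, na.rm = TRUE)) {
    stop("correlation matrix diagonal is not 1", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1] in ", p_path, call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) {
    stop("correlations outside [-1, 1] in ", r_path, call. = FALSE)
  }

  v <- nrow(r)
  p_raw <- matrix(0, v, v, dimnames = dimnames(r))
  p_adj <- p_raw
  p_raw[lower.tri(p_raw)] <- p[lower.tri(p)]
  p_raw[upper.tri(p_raw)] <- t(p)[upper.tri(p)]
  p_adj[upper.tri(p_adj)] <- p[upper.tri(p)]
  p_adj[lower.tri(p_adj)] <- t(p)[lower.tri(p)]

  structure(
    list(variable_ids = rownames(r), r = r, p_raw = p_raw, p_adj = p_adj,
         n_pairs = matrix(NA_integer_, v, v, dimnames = dimnames(r)),
         method = "unknown", adjust_method = "unknown", n_samples = NA_integer_),
    class = "cn_correlation"
  )
}

#' Write a three-column tab-delimited edge table
#'
#' The Cytoscape-compatible exchange format: one row per unordered edge,
#' tab-separated `source  target  r`, no header, 6 significant digits on
#' the weight. Reversed duplicates are collapsed before writing.
#'
#' @param edges Edge tibble (from [select_edges()] or [as_edge_table()]),
#'   needing at least `source` and `target` columns; a numeric `r` or
#'   `weight` column, if present, becomes the third column.
#' @param path Output path.
#' @param allow_empty Write an empty file for an empty edge set instead of
#'   erroring; default `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(edges, path, allow_empty = TRUE) {
  edges <- canonical_edges(tibble::as_tibble(edges))
  if (nrow(edges) == 0 && !allow_empty) {
    stop("edge table is empty", call. = FALSE)
  }
  wcol <- intersect(c("r", "weight"), names(edges))[1]
  lines <- if (nrow(edges) == 0) {
    character(0)
  } else if (!is.na(wcol)) {
    paste(edges$source, edges$target, fmt_num(edges[[wcol]]), sep = "\t")
  } else {
    paste(edges$source, edges$target, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge table into a network
#'
#' Reads a two- or three-column delimited edge list (the tab-delimited
#' format written by [write_edge_table()], or any adjacency table exported
#' from Cytoscape) and builds an undirected simple graph. A numeric third
#' column becomes the edge weight. Self-loop rows are skipped with a
#' warning; duplicate unordered pairs are collapsed keeping the first
#' occurrence.
#'
#' @param path Path to the edge table.
#' @param header Set `TRUE` to tolerate one header line.
#' @param sep Field separator, default tab.
#' @return An undirected igraph object (vertex attribute `name`, edge
#'   attribute `weight` when available).
#' @export
read_edge_table <- function(path, header = FALSE, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(empty_network())
  }
  tab <- utils::read.table(path, header = header, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (ncol(tab) < 2) {
    stop("edge table needs at least 2 columns: ", path, call. = FALSE)
  }
  edges <- tibble::tibble(source = as.character(tab[[1]]),
                          target = as.character(tab[[2]]))
  if (ncol(tab) >= 3 && is.numeric(tab[[3]])) {
    edges$r <- tab[[3]]
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning("skipped ", sum(loops), " self-loop row(s) in ", path,
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  build_network(edges, dedup = "first")
}

#' Export a network to SIF or GraphML
#'
#' SIF rows are `source<TAB>corr<TAB>target`, the fixed interaction type
#' `corr` marking a significant correlation. GraphML goes through igraph's
#' standard writer and round-trips vertex names and edge weights.
#'
#' @param net An undirected igraph network.
#' @param format `"sif"` or `"graphml"` (case-insensitive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(net, format = c("sif", "graphml"), path) {
  stopifnot(inherits(net, "igraph"))
  format <- tolower(format)
  format <- match.arg(format)
  if (format == "sif") {
    et <- as_edge_table(net)
    writeLines(paste(et$source, "corr", et$target, sep = "\t"), path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

write_labeled_csv <- function(mat, path) {
  df <- as.data.frame(apply(mat, 2, fmt_num), optional = TRUE)
  dimnames(df) <- dimnames(mat)
  utils::write.csv(df, path, quote = FALSE, row.names = TRUE)
}

read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.6g", v), character(1))
  out[is.na(x)] <- "NA"
  out
}
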