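#' Select significant edges from a correlation result
#'
#' Applies the two-factor significance rule of correlation-network
#' construction: a pair of variables becomes an edge when the magnitude of
#' its correlation reaches the critical value `r_min` AND its p-value falls
#' below the critical level `p_max`. By default the comparison is
#' \eqn{|r| \ge r_{min}} and \eqn{p < p_{max}} with `p` the adjusted
#' p-value (the q-value when the adjustment is an FDR procedure), matching
#' the common reporting style "r >= |0.7| and q < 0.05". Pairs whose
#' correlation is undefined (too few complete observations, constant
#' variable) are never selected. The sign of r is retained on the edge.
#'
#' @param result A `cn_correlation` object from [correlate()] or
#'   [read_correlation_tables()].
#' @param r_min Critical correlation magnitude in \[0, 1\], default 0.7.
#' @param p_max Critical significance level in (0, 1\], default 0.05.
#' @param use_adjusted Compare `p_max` against the adjusted p-values
#'   (default) or the raw ones.
#' @param strict_r,strict_p Inequality directions: default `|r| >= r_min`
#'   (non-strict) and `p < p_max` (strict).
#' @return An edge tibble with columns `source`, `target`, `r`, `p_raw`,
#'   `p_adj`, `n` — one row per selected unordered pair, source < target in
#'   variable order.
#' @examples
#' set.seed(7)
#' dm <- simulate_condition(synthetic_spec(seed = 7))
#' edges <- correlate(dm) |> select_edges(r_min = 0.7, p_max = 0.05)
#' head(edges)
#' @export
select_edges <- function(result, r_min = 0.7, p_max = 0.05,
                         use_adjusted = TRUE,
                         strict_r = FALSE, strict_p = TRUE) {
  stopifnot(inherits(result, "cn_correlation"))
  stopifnot(r_min >= 0, p_max > 0, p_max <= 1)
  ids <- result$variable_ids
  v <- length(ids)
  ut <- upper.tri(result$r)
  idx <- which(ut, arr.ind = TRUE)
  p_sel <- if (use_adjusted) result$p_adj else result$p_raw
  tab <- tibble::tibble(
    source = ids[idx[, "row"]],
    target = ids[idx[, "col"]],
    r = result$r[ut],
    p_raw = result$p_raw[ut],
    p_adj = result$p_adj[ut],
    n = as.integer(result$n_pairs[ut]),
    .p = p_sel[ut]
  )
  pass_r <- if (strict_r) abs(tab$r) > r_min else abs(tab$r) >= r_min
  pass_p <- if (strict_p) tab$.p < p_max else tab$.p <= p_max
  keep <- !is.na(tab$r) & !is.na(tab$.p) & pass_r & pass_p
  tab <- tab[keep, setdiff(names(tab), ".p"), drop = FALSE]
  dplyr::arrange(tab, .data$source, .data$target)
}

#' Build an undirected correlation network from an edge table
#'
#' Vertices are exactly the variables occurring in at least one edge —
#' a variable with no significant correlation never enters the network.
#' The result is a simple undirected igraph: no self-loops, no parallel
#' edges, the correlation stored as edge attribute `weight`.
#'
#' @param edges Edge tibble with `source`/`target` columns and optionally
#'   `r` (or `weight`), `p_raw`, `p_adj`.
#' @param classes Optional named character vector mapping vertex labels to
#'   a compound class (e.g. amino acid / sugar / carboxylic acid), stored
#'   as vertex attribute `class`.
#' @param dedup How to treat duplicate unordered pairs: `"error"` (default)
#'   rejects pairs whose weights conflict, `"first"` silently keeps the
#'   first occurrence.
#' @return An undirected igraph object.
#' @export
build_network <- function(edges, classes = NULL,
                          dedup = c("error", "first")) {
  dedup <- match.arg(dedup)
  edges <- canonical_edges(tibble::as_tibble(edges), dedup = dedup)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop edge(s)", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  wcol <- intersect(c("r", "weight"), names(edges))[1]
  if (nrow(edges) == 0) return(empty_network())
  el <- data.frame(from = edges$source, to = edges$target,
                   stringsAsFactors = FALSE)
  if (!is.na(wcol)) el$weight <- edges[[wcol]]
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  if (!is.null(classes)) {
    igraph::V(g)$class <- unname(classes[igraph::V(g)$name])
  }
  g
}

#' Tabular view of a network's edges
#'
#' @param net An undirected igraph network.
#' @return Tibble with `source`, `target` (source < target lexically,
#'   rows sorted) and `weight` when the network carries weights.
#' @export
as_edge_table <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::ecount(net) == 0) {
    return(tibble::tibble(source = character(0), target = character(0)))
  }
  ends <- igraph::as_edgelist(net, names = TRUE)
  out <- tibble::tibble(source = pmin(ends[, 1], ends[, 2]),
                        target = pmax(ends[, 1], ends[, 2]))
  if ("weight" %in% igraph::edge_attr_names(net)) {
    out$weight <- igraph::E(net)$weight
  }
  dplyr::arrange(out, .data$source, .data$target)
}

#' Set operations on condition-specific networks
#'
#' Differential comparison of two correlation networks built under
#' different conditions. Edge identity is the unordered label pair; weights
#' are ignored for membership (and taken from `a` when an edge exists in
#' both). All three operations return simple undirected graphs whose vertex
#' set is the vertices incident to at least one surviving edge — vertices
#' isolated by the operation are dropped, which is what makes the vertex
#' count of a difference network smaller than its parent's.
#'
#' @param a,b Undirected igraph networks with named vertices.
#' @return An undirected igraph network.
#' @name network-set-ops
#' @examples
#' a <- build_network(tibble::tibble(source = c("x", "y"),
#'                                   target = c("y", "z"), r = c(0.9, 0.8)))
#' b <- build_network(tibble::tibble(source = "y", target = "z", r = 0.75))
#' as_edge_table(network_difference(a, b)) # only x-y survives; z dropped
NULL

#' @rdname network-set-ops
#' @export
network_union <- function(a, b) {
  ea <- as_edge_table(a)
  eb <- as_edge_table(b)
  extra <- dplyr::anti_join(eb, ea, by = c("source", "target"))
  build_network(rename_weight(dplyr::bind_rows(ea, extra)), dedup = "first")
}

#' @rdname network-set-ops
#' @export
network_intersection <- function(a, b) {
  ea <- as_edge_table(a)
  eb <- as_edge_table(b)
  keep <- dplyr::semi_join(ea, eb, by = c("source", "target"))
  build_network(rename_weight(keep), dedup = "first")
}

#' @rdname network-set-ops
#' @export
network_difference <- function(a, b) {
  ea <- as_edge_table(a)
  eb <- as_edge_table(b)
  keep <- dplyr::anti_join(ea, eb, by = c("source", "target"))
  build_network(rename_weight(keep), dedup = "first")
}

empty_network <- function() {
  igraph::make_empty_graph(n = 0, directed = FALSE)
}

rename_weight <- function(edges) {
  if ("weight" %in% names(edges) && !"r" %in% names(edges)) {
    names(edges)[names(edges) == "weight"] <- "r"
  }
  edges
}

# canonicalize an edge tibble: source < target lexically, self-loops kept
# for the caller to reject, duplicates resolved per `dedup`
canonical_edges <- function(edges, dedup = c("first", "error")) {
  dedup <- match.arg(dedup)
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (nrow(edges) == 0) return(edges)
  s <- as.character(edges$source)
  t <- as.character(edges$target)
  edges$source <- pmin(s, t)
  edges$target <- pmax(s, t)
  key <- paste(edges$source, edges$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    wcol <- intersect(c("r", "weight"), names(edges))[1]
    if (dedup == "error" && !is.na(wcol)) {
      w <- edges[[wcol]]
      first <- match(key, key)
      conflict <- abs(w - w[first]) > 1e-9
      conflict[is.na(conflict)] <- !(is.na(w) & is.na(w[first]))[is.na(conflict)]
      if (any(conflict)) {
        stop("duplicate edge(s) with conflicting weights: ",
             paste(unique(paste0(edges$source, "-", edges$target)[conflict]),
                   collapse = ", "), call. = FALSE)
      }
    }
    edges <- edges[!dup, , drop = FALSE]
  }
  edges
}
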