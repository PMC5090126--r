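#' Global and per-element network topology report
#'
#' Computes the standard topology metrics used to characterize correlation
#' networks, with the conventions of Cytoscape's NetworkAnalyzer for
#' undirected graphs: all shortest paths are unweighted hop counts
#' (correlation weights are attributes, not distances), vertex betweenness
#' is normalized by \eqn{(v-1)(v-2)/2} over the whole graph, the diameter
#' is taken over the largest connected component, and the average shortest
#' path averages over all mutually reachable ordered pairs. Both the global
#' transitivity (3 x triangles / connected triples — the probability that
#' two neighbours of a vertex are themselves connected) and the mean local
#' clustering coefficient are reported; "transitivity" in the global table
#' refers to the former.
#'
#' @param net An undirected igraph network.
#' @return A `cn_topology` object: list with `global` (one-row tibble:
#'   `vertices`, `edges`, `density`, `diameter`, `transitivity`,
#'   `transitivity_defined`, `mean_clustering`, `avg_shortest_path`,
#'   `components`), `vertices` (tibble: `label`, `class`, `degree`,
#'   `betweenness`, `clustering`), `edges` (tibble: `source`, `target`,
#'   `weight`, `betweenness`), and `power_law` (list: `exponent`,
#'   `r_squared`, `n_degrees`). Deterministic for a fixed graph.
#' @seealso [rank_hubs()], [write_topology()], [autoplot.cn_topology()]
#' @export
analyze_topology <- function(net) {
  stopifnot(inherits(net, "igraph"), !igraph::is_directed(net))
  v <- igraph::vcount(net)
  e <- igraph::ecount(net)
  labels <- if (v > 0) igraph::V(net)$name else character(0)
  classes <- if (v > 0 && "class" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$class
  } else {
    rep(NA_character_, v)
  }

  deg <- vertex_degrees(net)
  btw <- vertex_betweenness(net)
  clus <- clustering_coefficients(net)
  comp <- if (v > 0) igraph::components(net)$no else 0L

  trans <- global_transitivity(net)
  vertices <- tibble::tibble(
    label = labels, class = classes,
    degree = unname(deg), betweenness = unname(btw),
    clustering = unname(clus)
  )
  vertices <- dplyr::arrange(vertices, .data$label)

  edges <- as_edge_table(net)
  if (e > 0) {
    eb <- edge_betweenness_values(net)
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    edges$betweenness <- eb[edges_key_order(net, edges)]
  } else {
    edges$weight <- numeric(0)
    edges$betweenness <- numeric(0)
  }

  global <- tibble::tibble(
    vertices = v, edges = e,
    density = net_density(net),
    diameter = net_diameter(net),
    transitivity = trans$value,
    transitivity_defined = trans$defined,
    mean_clustering = if (v > 0) mean(clus) else NA_real_,
    avg_shortest_path = avg_shortest_path(net),
    components = comp
  )

  structure(
    list(global = global, vertices = vertices, edges = edges,
         power_law = fit_power_law(net)),
    class = "cn_topology"
  )
}

#' Network density
#'
#' The ratio of existing to possible edges, \eqn{2e / (v(v-1))}.
#'
#' @param net An undirected igraph network.
#' @return Density in \[0, 1\]; `NA` for fewer than 2 vertices.
#' @export
net_density <- function(net) {
  v <- igraph::vcount(net)
  if (v < 2) return(NA_real_)
  2 * igraph::ecount(net) / (v * (v - 1))
}

#' Vertex degrees
#' @param net An undirected igraph network.
#' @return Named integer vector; always sums to twice the edge count.
#' @export
vertex_degrees <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Normalized vertex betweenness centrality
#'
#' The fraction of all-pairs shortest paths passing through each vertex,
#' normalized to \[0, 1\] by \eqn{(v-1)(v-2)/2} with v the whole-graph
#' vertex count; unreachable pairs contribute nothing. Graphs with fewer
#' than 3 vertices get all zeros.
#'
#' @param net An undirected igraph network.
#' @return Named numeric vector in \[0, 1\].
#' @export
vertex_betweenness <- function(net) {
  v <- igraph::vcount(net)
  if (v == 0) return(stats::setNames(numeric(0), character(0)))
  if (v < 3) {
    return(stats::setNames(numeric(v), igraph::V(net)$name))
  }
  raw <- igraph::betweenness(net, directed = FALSE, weights = NA)
  raw / ((v - 1) * (v - 2) / 2)
}

#' Edge betweenness
#'
#' Unnormalized count of shortest paths (fractionally, when a pair has
#' several) running along each edge, each unordered vertex pair counted
#' once.
#'
#' @param net An undirected igraph network.
#' @return Numeric vector in igraph's edge order.
#' @export
edge_betweenness_values <- function(net) {
  if (igraph::ecount(net) == 0) return(numeric(0))
  igraph::edge_betweenness(net, directed = FALSE, weights = NA)
}

#' Local clustering coefficients
#'
#' For a vertex of degree >= 2, the fraction of its neighbour pairs that
#' are connected; vertices of degree < 2 get 0.
#'
#' @param net An undirected igraph network.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficients <- function(net) {
  v <- igraph::vcount(net)
  if (v == 0) return(stats::setNames(numeric(0), character(0)))
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  stats::setNames(cc, igraph::V(net)$name)
}

#' Global transitivity
#'
#' \eqn{3 T / t} with T the number of triangles and t the number of
#' connected triples \eqn{\sum_v \binom{deg(v)}{2}}; the probability to
#' form cliques. Undefined (no connected triple) is reported as value 0
#' with `defined = FALSE`.
#'
#' @param net An undirected igraph network.
#' @return List with `value` and `defined`.
#' @export
global_transitivity <- function(net) {
  x <- igraph::transitivity(net, type = "global")
  if (is.nan(x) || is.na(x)) list(value = 0, defined = FALSE)
  else list(value = x, defined = TRUE)
}

#' Diameter over the largest connected component
#'
#' The maximal shortest path (unweighted hop count) between any two
#' vertices of the largest connected component (largest by vertex count;
#' ties broken by first occurrence). Check the component count in
#' [analyze_topology()]'s global table when interpreting this on a
#' disconnected graph.
#'
#' @param net An undirected igraph network.
#' @return Non-negative integer; `NA` for an empty graph.
#' @export
net_diameter <- function(net) {
  v <- igraph::vcount(net)
  if (v == 0) return(NA_integer_)
  if (igraph::ecount(net) == 0) return(0L)
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  as.integer(igraph::diameter(sub, directed = FALSE, weights = NA,
                              unconnected = FALSE))
}

#' Average shortest path length
#'
#' Mean hop distance over all mutually reachable ordered vertex pairs of
#' the whole graph; unreachable pairs are excluded from the average.
#'
#' @param net An undirected igraph network.
#' @return Numeric; `NA` when no two vertices are connected.
#' @export
avg_shortest_path <- function(net) {
  if (igraph::vcount(net) < 2 || igraph::ecount(net) == 0) return(NA_real_)
  igraph::mean_distance(net, directed = FALSE, weights = NA,
                        unconnected = TRUE)
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line on log(count) versus log(degree) over the non-zero
#' bins of the degree histogram (degrees >= 1). Returns the slope magnitude
#' as the exponent and the squared correlation of the fit. At least 3
#' distinct degree values are required; otherwise the fit is undefined and
#' `exponent`/`r_squared` are `NA`.
#'
#' @param net An undirected igraph network.
#' @return List with `exponent`, `r_squared`, `n_degrees` (number of
#'   distinct non-zero degree values).
#' @export
fit_power_law <- function(net) {
  deg <- vertex_degrees(net)
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3) {
    return(list(exponent = NA_real_, r_squared = NA_real_,
                n_degrees = length(k)))
  }
  fit <- stats::lm(log(cnt) ~ log(k))
  # a flat histogram has no explained variance; r^2 is 0, not NaN
  r2 <- if (stats::var(log(cnt)) == 0) 0 else stats::cor(log(cnt), log(k))^2
  list(exponent = abs(unname(stats::coef(fit)[2])),
       r_squared = r2,
       n_degrees = length(k))
}

#' Rank hub vertices
#'
#' Orders the vertices of a topology report by betweenness centrality
#' (descending), breaking ties by degree (descending) and then label
#' (ascending) — the ordering used to present hub metabolites.
#'
#' @param report A `cn_topology` object from [analyze_topology()].
#' @return The per-vertex tibble, reordered.
#' @export
rank_hubs <- function(report) {
  stopifnot(inherits(report, "cn_topology"))
  dplyr::arrange(report$vertices, dplyr::desc(.data$betweenness),
                 dplyr::desc(.data$degree), .data$label)
}

#' Write topology report CSV files
#'
#' Writes `<prefix>vertices.csv` (label, class, degree, betweenness,
#' clustering; hub order) and `<prefix>global.csv` (the one-row global
#' metrics table).
#'
#' @param report A `cn_topology` object.
#' @param prefix Path prefix.
#' @return Invisibly, the two paths.
#' @export
write_topology <- function(report, prefix = "") {
  stopifnot(inherits(report, "cn_topology"))
  v_path <- paste0(prefix, "vertices.csv")
  g_path <- paste0(prefix, "global.csv")
  utils::write.csv(rank_hubs(report), v_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(report$global, g_path, row.names = FALSE, quote = FALSE)
  invisible(c(vertices = v_path, global = g_path))
}

#' @export
print.cn_topology <- function(x, ...) {
  g <- x$global
  cat("Network topology: ", g$vertices, " vertices, ", g$edges, " edges (",
      g$components, " component", if (g$components != 1) "s", ")\n", sep = "")
  cat(sprintf("  density %.3f | diameter %s | transitivity %.3f%s | avg path %.3f\n",
              g$density, g$diameter, g$transitivity,
              if (!g$transitivity_defined) " (undefined)" else "",
              g$avg_shortest_path))
  top <- utils::head(rank_hubs(x), 3)
  if (nrow(top) > 0) {
    cat("  top hubs: ",
        paste0(top$label, " (b=", sprintf("%.3f", top$betweenness),
               ", d=", top$degree, ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# map edge-betweenness values (igraph edge order) onto the sorted edge table
edges_key_order <- function(net, edges) {
  ends <- igraph::as_edgelist(net, names = TRUE)
  key_g <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
                 sep = "\r")
  key_t <- paste(edges$source, edges$target, sep = "\r")
  match(key_t, key_g)
}
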