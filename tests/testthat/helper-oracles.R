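# Independent brute-force oracles for the topology metrics and the BH
# adjustment. Deliberately naive: adjacency matrices, hand-rolled BFS, and
# explicit shortest-path enumeration, so they share no code with the
# implementation they check.

# BFS hop distances from source s on a 0/1 adjacency matrix
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (!is.finite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_dist_matrix <- function(adj) {
  n <- nrow(adj)
  t(vapply(seq_len(n), function(s) oracle_bfs(adj, s), numeric(n)))
}

# all shortest paths s -> t as lists of vertex indices, via DFS restricted
# to the shortest-path DAG
oracle_shortest_paths <- function(adj, s, t) {
  d_to_t <- oracle_bfs(adj, t)
  if (!is.finite(d_to_t[s])) return(list())
  paths <- list()
  walk <- function(path, v) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(adj[v, ] == 1)) {
      if (d_to_t[w] == d_to_t[v] - 1) walk(c(path, w), w)
    }
  }
  walk(s, s)
  paths
}

# normalized vertex betweenness by explicit enumeration over unordered pairs
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- oracle_shortest_paths(adj, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# unnormalized edge betweenness, keyed "i-j" with i < j
oracle_edge_betweenness <- function(adj) {
  n <- nrow(adj)
  keys <- character(0)
  vals <- numeric(0)
  add <- function(i, j, x) {
    k <- paste(min(i, j), max(i, j), sep = "-")
    hit <- match(k, keys)
    if (is.na(hit)) {
      keys <<- c(keys, k)
      vals <<- c(vals, x)
    } else {
      vals[hit] <<- vals[hit] + x
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) if (adj[i, j] == 1) add(i, j, 0)
  }
  if (n >= 2) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        paths <- oracle_shortest_paths(adj, s, t)
        if (length(paths) == 0) next
        for (p in paths) {
          for (k in seq_len(length(p) - 1)) {
            add(p[k], p[k + 1], 1 / length(paths))
          }
        }
      }
    }
  }
  stats::setNames(vals, keys)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / choose(k, 2)
  }, numeric(1))
}

oracle_transitivity <- function(adj) {
  deg <- rowSums(adj)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(NA_real_)
  tri <- sum(diag(adj %*% adj %*% adj)) / 6
  3 * tri / triples
}

oracle_diameter <- function(adj) {
  # over the largest connected component (vertex count, first on ties)
  n <- nrow(adj)
  d <- oracle_dist_matrix(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- tabulate(comp)
  big <- which(comp == which.max(sizes))
  if (length(big) < 2) return(0)
  max(d[big, big])
}

oracle_avg_path <- function(adj) {
  d <- oracle_dist_matrix(adj)
  diag(d) <- NA
  vals <- d[is.finite(d) & !is.na(d)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

oracle_component_count <- function(adj) {
  d <- oracle_dist_matrix(adj)
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(d[v, ])] <- cid
    }
  }
  cid
}

# step-up BH oracle: adjusted_i = min over k with p_(k) >= p_i of p_(k)*m/k
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(seq(i, n), function(k) ranked[k] * m / k, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# random Erdos-Renyi adjacency matrix on n vertices
rand_adjacency <- function(n, p_edge) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1
    }
  }
  adj
}

adjacency_to_network <- function(adj) {
  n <- nrow(adj)
  labels <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(g)
  }
  build_network(tibble::tibble(source = labels[idx[, 1]],
                               target = labels[idx[, 2]],
                               r = 1))
}

# align a network's per-vertex vector back to adjacency index order
by_adj_order <- function(values, adj) {
  labels <- sprintf("v%02d", seq_len(nrow(adj)))
  present <- intersect(labels, names(values))
  out <- stats::setNames(numeric(length(labels)), labels)
  out[present] <- values[present]
  out
}
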