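# small named graphs used across the topology tests

edge_tbl <- function(source, target, r = NULL) {
  tab <- tibble::tibble(source = source, target = target)
  if (!is.null(r)) tab$r <- r
  tab
}

triangle_net <- function(labels = c("a", "b", "c")) {
  build_network(edge_tbl(labels[c(1, 2, 1)], labels[c(2, 3, 3)],
                         r = c(0.9, 0.8, 0.7)))
}

path_net <- function(n, prefix = "p") {
  labels <- paste0(prefix, seq_len(n))
  build_network(edge_tbl(labels[-n], labels[-1], r = rep(0.8, n - 1)))
}

star_net <- function(n_leaves = 4) {
  build_network(edge_tbl(rep("hub", n_leaves),
                         paste0("leaf", seq_len(n_leaves)),
                         r = rep(0.9, n_leaves)))
}

complete_net <- function(n) {
  labels <- paste0("k", seq_len(n))
  pairs <- utils::combn(labels, 2)
  build_network(edge_tbl(pairs[1, ], pairs[2, ], r = rep(0.9, ncol(pairs))))
}

# two triangles joined by a single bridge edge
barbell_net <- function() {
  build_network(edge_tbl(
    c("a", "b", "a", "d", "e", "d", "c"),
    c("b", "c", "c", "e", "f", "f", "d"),
    r = rep(0.8, 7)
  ))
}

drop_isolated <- function(adj) {
  keep <- rowSums(adj) > 0
  adj[keep, keep, drop = FALSE]
}

write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
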